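#' Labelled office floor plans
#'
#' Builds the labelled-polygon frame for zone occupancy analysis: a 371-m2
#' office before and after an activity-based-working renovation. The
#' pre-renovation layout has a traditional structure (one main aisle, one
#' around-workstation aisle, dedicated desks and a single shared
#' workstation); the post-renovation layout introduces round aisles with two
#' multiple-usage aisles and four shared height-adjustable workstations.
#' Coordinates are floor-plan meters; every zone carries a category, an
#' overlap-resolution priority (workstations above aisles) and its polygon
#' area.
#'
#' @param layout `"pre"` or `"post"`.
#' @return an `office_plan`: a tibble with columns `label`, `category`,
#'   `priority`, `area_m2` and a `polygon` list-column of closed x/y
#'   coordinate matrices.
#' @export
office_plan <- function(layout = c("pre", "post")) {
  layout <- match.arg(layout)
  rect <- function(x0, y0, x1, y1) {
    cbind(x = c(x0, x1, x1, x0, x0), y = c(y0, y0, y1, y1, y1)[c(1, 2, 3, 4, 1)])
  }
  # 26 x 14.3 m room (~371 m2) partitioned into non-overlapping rectangles
  zones <- if (layout == "pre") {
    list(
      list("main_aisle", "main_aisle", 1L, rect(0, 6.3, 26, 8.3)),
      list("around_ws_aisle", "around_workstation_aisle", 1L, rect(0, 4.6, 26, 6.3)),
      list("dedicated_ws", "dedicated_workstation", 2L, rect(0, 8.3, 26, 14.3)),
      list("shared_ws", "shared_workstation", 2L, rect(0, 0, 26, 4.6))
    )
  } else {
    list(
      list("main_aisle", "main_aisle", 1L, rect(0, 6.3, 26, 8.3)),
      list("multiple_usage_aisle_1", "multiple_usage_aisle", 1L, rect(0, 8.3, 10, 9.8)),
      list("multiple_usage_aisle_2", "multiple_usage_aisle", 1L, rect(10, 8.3, 26, 9.8)),
      list("around_ws_aisle", "around_workstation_aisle", 1L, rect(0, 4.8, 26, 6.3)),
      list("dedicated_ws", "dedicated_workstation", 2L, rect(0, 9.8, 26, 14.3)),
      list("shared_ws_1", "shared_workstation", 2L, rect(0, 0, 6.5, 4.8)),
      list("shared_ws_2", "shared_workstation", 2L, rect(6.5, 0, 13, 4.8)),
      list("shared_ws_3", "shared_workstation", 2L, rect(13, 0, 19.5, 4.8)),
      list("shared_ws_4", "shared_workstation", 2L, rect(19.5, 0, 26, 4.8))
    )
  }
  plan <- tibble::tibble(
    label = vapply(zones, `[[`, character(1), 1),
    category = vapply(zones, `[[`, character(1), 2),
    priority = vapply(zones, `[[`, integer(1), 3),
    polygon = lapply(zones, `[[`, 4)
  )
  plan$area_m2 <- vapply(plan$polygon, polygon_area, numeric(1))
  stopifnot(all(plan$area_m2 > 0))
  class(plan) <- c("office_plan", class(plan))
  plan
}

# shoelace area of a closed ring
polygon_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  if (n < 4 || x[1] != x[n] || y[1] != y[n]) {
    stop("polygon ring must be closed (first point repeated last)",
         call. = FALSE)
  }
  abs(sum(x[-n] * y[-1] - x[-1] * y[-n])) / 2
}

#' Write / read an office plan as GeoJSON
#'
#' Plans are serialized as a `FeatureCollection` of `Polygon` features with
#' properties `label`, `category`, `priority` and `area_m2`; coordinates are
#' floor meters, not geographic.
#'
#' @param plan an [office_plan()].
#' @param path file path.
#' @return `write_plan_geojson` returns `path` invisibly; `read_plan_geojson`
#'   returns an `office_plan`.
#' @export
write_plan_geojson <- function(plan, path) {
  features <- lapply(seq_len(nrow(plan)), function(i) {
    poly <- plan$polygon[[i]]
    list(
      type = "Feature",
      properties = list(label = plan$label[i], category = plan$category[i],
                        priority = plan$priority[i],
                        area_m2 = plan$area_m2[i]),
      geometry = list(type = "Polygon",
                      coordinates = list(unname(lapply(
                        seq_len(nrow(poly)),
                        function(j) c(poly[j, 1], poly[j, 2])))))
    )
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = features),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_plan_geojson
#' @export
read_plan_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  zones <- lapply(gj$features, function(f) {
    if (!identical(f$geometry$type, "Polygon")) {
      stop("expected Polygon features", call. = FALSE)
    }
    ring <- do.call(rbind, lapply(f$geometry$coordinates[[1]],
                                  function(pt) as.numeric(unlist(pt))))
    colnames(ring) <- c("x", "y")
    if (nrow(ring) < 4 ||
        any(ring[1, ] != ring[nrow(ring), ])) {
      stop(sprintf("zone '%s': polygon ring must be closed",
                   f$properties$label), call. = FALSE)
    }
    list(label = f$properties$label, category = f$properties$category,
         priority = as.integer(f$properties$priority),
         area_m2 = as.numeric(f$properties$area_m2), polygon = ring)
  })
  plan <- tibble::tibble(
    label = vapply(zones, `[[`, character(1), "label"),
    category = vapply(zones, `[[`, character(1), "category"),
    priority = vapply(zones, `[[`, integer(1), "priority"),
    polygon = lapply(zones, `[[`, "polygon"),
    area_m2 = vapply(zones, `[[`, numeric(1), "area_m2")
  )
  class(plan) <- c("office_plan", class(plan))
  plan
}
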
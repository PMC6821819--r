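#' Nest geometry configuration
#'
#' Describes the one-chamber nest: outer dimensions in mm, the entrance
#' position on the boundary, and the regular grid used for occupancy
#' analyses (default 6 x 5 = 30 cells of 9.33 x 8.2 mm for a 56 x 41 mm
#' chamber, roughly two ant lengths per cell side).
#'
#' The "foreground" is the half of the nest nearer the entrance, split
#' perpendicular to the axis the entrance sits on; it is derived from the
#' entrance position (an entrance on a vertical wall splits the nest in x,
#' on a horizontal wall in y).
#'
#' @param width_mm,height_mm Nest inner dimensions (mm).
#' @param entrance_mm Entrance position `c(x, y)` in mm, on the boundary.
#'   Default: middle of the left wall.
#' @param grid_ncol,grid_nrow Grid shape (columns x rows).
#' @return Object of class `nest_geometry`.
#' @export
nest_geometry <- function(width_mm = 56, height_mm = 41,
                          entrance_mm = c(0, height_mm / 2),
                          grid_ncol = 6, grid_nrow = 5) {
  stopifnot(width_mm > 0, height_mm > 0, length(entrance_mm) == 2,
            grid_ncol >= 1, grid_nrow >= 1)
  on_x_wall <- entrance_mm[1] %in% c(0, width_mm)
  on_y_wall <- entrance_mm[2] %in% c(0, height_mm)
  if (!on_x_wall && !on_y_wall) stop("entrance must lie on the nest boundary")
  structure(list(width_mm = width_mm, height_mm = height_mm,
                 entrance_mm = as.numeric(entrance_mm),
                 grid_ncol = as.integer(grid_ncol),
                 grid_nrow = as.integer(grid_nrow),
                 cell_w_mm = width_mm / grid_ncol,
                 cell_h_mm = height_mm / grid_nrow,
                 split_axis = if (on_x_wall) "x" else "y"),
            class = "nest_geometry")
}

#' @export
print.nest_geometry <- function(x, ...) {
  cat(sprintf("nest %g x %g mm, entrance at (%g, %g), grid %d x %d (cells %.2f x %.2f mm)\n",
              x$width_mm, x$height_mm, x$entrance_mm[1], x$entrance_mm[2],
              x$grid_ncol, x$grid_nrow, x$cell_w_mm, x$cell_h_mm))
  invisible(x)
}

in_foreground <- function(x_mm, y_mm, geometry) {
  if (geometry$split_axis == "x") {
    half <- geometry$width_mm / 2
    if (geometry$entrance_mm[1] == 0) x_mm < half else x_mm >= half
  } else {
    half <- geometry$height_mm / 2
    if (geometry$entrance_mm[2] == 0) y_mm < half else y_mm >= half
  }
}

entrance_distance_cm <- function(x_mm, y_mm, geometry) {
  sqrt((x_mm - geometry$entrance_mm[1])^2 +
       (y_mm - geometry$entrance_mm[2])^2) / 10
}

#' Per-ant gravity centres of trophallactic events
#'
#' For each ant participating in at least one event, computes the gravity
#' centre (centroid) of the positions of all events it took part in — as
#' donor or receiver — and the mean Euclidean distance of those events to
#' the centroid, in cm. The distance is 0 for ants with a single event.
#' Flags allow the role-restricted subgroups (ants that gave at least once
#' vs ants that only received) to be compared.
#'
#' @param events Merged event data.frame.
#' @param castes Caste map.
#' @return data.frame with one row per participating ant: `ant`, `caste`,
#'   `gx_mm`, `gy_mm`, `mean_dist_cm`, `n_events`, `gave_any`,
#'   `received_any`.
#' @export
gravity_summaries <- function(events, castes) {
  parts <- rbind(
    data.frame(ant = events$donor, x = events$x_mm, y = events$y_mm,
               role = "given", stringsAsFactors = FALSE),
    data.frame(ant = events$receiver, x = events$x_mm, y = events$y_mm,
               role = "received", stringsAsFactors = FALSE)
  )
  ants <- sort(unique(parts$ant))
  rows <- lapply(ants, function(a) {
    p <- parts[parts$ant == a, , drop = FALSE]
    gx <- mean(p$x)
    gy <- mean(p$y)
    data.frame(ant = a,
               caste = caste_of(castes, a),
               gx_mm = gx, gy_mm = gy,
               mean_dist_cm = mean(sqrt((p$x - gx)^2 + (p$y - gy)^2)) / 10,
               n_events = nrow(p),
               gave_any = any(p$role == "given"),
               received_any = any(p$role == "received"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Bin positions onto the nest occupancy grid
#'
#' Assigns each point to exactly one grid cell using half-open cells whose
#' far (right/top) edges are closed, so in-bounds points on the outer
#' boundary fall in the last cell. Counts are accumulated per time window.
#'
#' @param points data.frame with columns `minute`, `x_mm`, `y_mm` — either
#'   snapshot ant positions (occupancy) or event positions (trophallaxis).
#' @param geometry [nest_geometry()].
#' @param window_min Window length in minutes (default 10).
#' @return Long-format data.frame: `window` (0-based), `col`, `row` (0-based
#'   from the origin corner), `count`, covering every cell of every spanned
#'   window (zeros included).
#' @export
occupancy_grid <- function(points, geometry, window_min = 10) {
  if (nrow(points) > 0) {
    out <- points$x_mm < 0 | points$x_mm > geometry$width_mm |
           points$y_mm < 0 | points$y_mm > geometry$height_mm
    if (any(out)) {
      stop("point(s) outside nest bounds in row(s): ",
           paste(utils::head(which(out), 5L), collapse = ", "))
    }
  }
  nc <- geometry$grid_ncol
  nr <- geometry$grid_nrow
  col <- pmin(floor(points$x_mm / geometry$cell_w_mm), nc - 1L)
  row <- pmin(floor(points$y_mm / geometry$cell_h_mm), nr - 1L)
  window <- floor(points$minute / window_min)
  windows <- if (nrow(points) > 0) 0:max(window) else integer(0)
  grid <- expand.grid(window = windows, col = 0:(nc - 1), row = 0:(nr - 1))
  key <- paste(grid$window, grid$col, grid$row)
  tab <- table(paste(window, col, row))
  grid$count <- as.integer(tab[key])
  grid$count[is.na(grid$count)] <- 0L
  grid[order(grid$window, grid$col, grid$row), , drop = FALSE]
}

#' Spatial correlation between ant aggregation and trophallaxis
#'
#' Spearman rank correlation between two grids (e.g. snapshot ant counts vs
#' event counts) over cells, after aggregating counts across windows
#' (`per_window = TRUE` instead correlates within each window). A constant
#' grid gives a flagged degenerate result with `rho = NA`.
#'
#' @param grid_a,grid_b Grids from [occupancy_grid()] with the same geometry.
#' @param per_window Correlate per window instead of aggregating.
#' @return List with `rho`, `p`, `n_cells`, `degenerate` (or a data.frame of
#'   per-window results).
#' @export
grid_correlation <- function(grid_a, grid_b, per_window = FALSE) {
  one <- function(a, b) {
    ka <- paste(a$col, a$row)
    agg_a <- tapply(a$count, ka, sum)
    agg_b <- tapply(b$count, paste(b$col, b$row), sum)
    agg_b <- agg_b[names(agg_a)]
    if (length(agg_a) != length(agg_b) || anyNA(agg_b)) {
      stop("grids do not share a geometry")
    }
    if (stats::var(agg_a) == 0 || stats::var(agg_b) == 0) {
      return(list(rho = NA_real_, p = NA_real_, n_cells = length(agg_a),
                  degenerate = TRUE))
    }
    ct <- suppressWarnings(
      stats::cor.test(as.numeric(agg_a), as.numeric(agg_b),
                      method = "spearman"))
    list(rho = unname(ct$estimate), p = ct$p.value, n_cells = length(agg_a),
         degenerate = FALSE)
  }
  if (!per_window) return(one(grid_a, grid_b))
  windows <- intersect(unique(grid_a$window), unique(grid_b$window))
  do.call(rbind, lapply(windows, function(w) {
    r <- one(grid_a[grid_a$window == w, ], grid_b[grid_b$window == w, ])
    data.frame(window = w, rho = r$rho, p = r$p, degenerate = r$degenerate)
  }))
}

#' Foreground donation shares by caste
#'
#' Splits the events donated by each caste into foreground (the nest half
#' nearer the entrance) vs background, reports each caste's foreground
#' proportion, and tests the 2 x 2 caste-by-half table with a chi-square
#' test. With `role = "received"` the receiver's caste classifies the event.
#'
#' @param events Merged event data.frame.
#' @param castes Caste map.
#' @param geometry [nest_geometry()].
#' @param role `"given"` (default) or `"received"`.
#' @return List with `table` (per-caste foreground/total counts and shares),
#'   `chisq`, `p`, `degenerate`.
#' @export
foreground_shares <- function(events, castes, geometry, role = c("given", "received")) {
  role <- match.arg(role)
  who <- if (role == "given") events$donor else events$receiver
  caste <- caste_of(castes, who)
  fg <- in_foreground(events$x_mm, events$y_mm, geometry)
  if (!all(c("F", "NF") %in% caste)) {
    stop("foreground_shares requires at least one event per caste")
  }
  tab <- data.frame(
    caste = c("F", "NF"),
    foreground = c(sum(fg & caste == "F"), sum(fg & caste == "NF")),
    total = c(sum(caste == "F"), sum(caste == "NF")),
    stringsAsFactors = FALSE
  )
  tab$share <- tab$foreground / tab$total
  m <- cbind(tab$foreground, tab$total - tab$foreground)
  degenerate <- any(colSums(m) == 0)
  if (degenerate) {
    chisq <- NA_real_
    p <- NA_real_
  } else {
    ct <- suppressWarnings(stats::chisq.test(m))
    chisq <- unname(ct$statistic)
    p <- ct$p.value
  }
  list(table = tab, chisq = chisq, p = p, degenerate = degenerate)
}

#' Entrance-distance of events over time
#'
#' Mean Euclidean distance (cm) from the event positions to the nest
#' entrance, per time window and caste of the donor (the ant initiating the
#' transfer). Windows with no events for a group are absent from the output.
#'
#' @param events Merged event data.frame.
#' @param geometry [nest_geometry()].
#' @param castes Optional caste map; when supplied, results are grouped by
#'   donor caste, otherwise pooled.
#' @param window_min Window length in minutes.
#' @return data.frame with columns `window`, `caste` (or `"all"`),
#'   `mean_dist_cm`, `n_events`.
#' @export
entrance_distance_series <- function(events, geometry, castes = NULL,
                                     window_min = 10) {
  d <- entrance_distance_cm(events$x_mm, events$y_mm, geometry)
  w <- floor(events$start_min / window_min)
  grp <- if (is.null(castes)) rep("all", nrow(events))
         else caste_of(castes, events$donor)
  agg <- stats::aggregate(d, by = list(window = w, caste = grp),
                          FUN = function(v) c(mean = mean(v), n = length(v)))
  out <- data.frame(window = agg$window, caste = agg$caste,
                    mean_dist_cm = agg$x[, "mean"],
                    n_events = as.integer(agg$x[, "n"]),
                    stringsAsFactors = FALSE)
  out[order(out$caste, out$window), , drop = FALSE]
}

#' Spatial heterogeneity of event locations
#'
#' Tests whether events are homogeneously distributed over the nest grid by
#' comparing the Pearson chi-square of the observed per-cell event counts
#' (against the uniform expectation) with its distribution under repeated
#' uniform random placement of the same number of events. A Z-test
#' summarises the deviation; clustered events give large positive Z.
#'
#' @param events Merged event data.frame.
#' @param geometry [nest_geometry()].
#' @param n_replicates Null ensemble size.
#' @param seed Integer master seed.
#' @return `z_test_result` with the ensemble attached.
#' @export
spatial_uniformity_test <- function(events, geometry, n_replicates = 1000,
                                    seed = 1) {
  stopifnot(nrow(events) >= 1)
  n_cells <- geometry$grid_ncol * geometry$grid_nrow
  cell_counts <- function(x, y) {
    col <- pmin(floor(x / geometry$cell_w_mm), geometry$grid_ncol - 1L)
    row <- pmin(floor(y / geometry$cell_h_mm), geometry$grid_nrow - 1L)
    tabulate(row * geometry$grid_ncol + col + 1L, nbins = n_cells)
  }
  chisq_stat <- function(counts) {
    e <- sum(counts) / n_cells
    sum((counts - e)^2 / e)
  }
  obs <- chisq_stat(cell_counts(events$x_mm, events$y_mm))
  m <- nrow(events)
  values <- vapply(seq_len(n_replicates), function(r) {
    set.seed(seed + r)
    chisq_stat(cell_counts(stats::runif(m, 0, geometry$width_mm),
                           stats::runif(m, 0, geometry$height_mm)))
  }, numeric(1))
  res <- z_test(obs, values, sidedness = "greater")
  res$ensemble <- values
  res
}
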
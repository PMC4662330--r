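ellipse_axes <- function(area, aspect) {
  a <- sqrt(area * aspect / pi)
  c(a = a, b = a / aspect)
}

# pixel-center grid covering [-half_w, half_w] x [-half_h, half_h]
pixel_centers <- function(half_w, half_h, px_per_um) {
  step <- 1 / px_per_um
  nx <- ceiling(2 * half_w * px_per_um)
  ny <- ceiling(2 * half_h * px_per_um)
  list(x = (seq_len(nx) - (nx + 1) / 2) * step,
       y = (seq_len(ny) - (ny + 1) / 2) * step)
}

# cells of a pixel grid whose centers fall inside a rotated ellipse
ellipse_cells <- function(xv, yv, cx, cy, a, b, theta) {
  ix <- which(abs(xv - cx) <= sqrt(a^2 * cos(theta)^2 + b^2 * sin(theta)^2) + 1e-12)
  iy <- which(abs(yv - cy) <= sqrt(a^2 * sin(theta)^2 + b^2 * cos(theta)^2) + 1e-12)
  if (!length(ix) || !length(iy)) return(cbind(integer(), integer()))
  dx <- rep(xv[ix] - cx, times = length(iy))
  dy <- rep(yv[iy] - cy, each = length(ix))
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  inside <- u^2 + v^2 <= 1
  cbind(rep(ix, times = length(iy))[inside],
        rep(iy, each = length(ix))[inside])
}

#' Build an idealised cross-section layout for one needle
#'
#' Geometric surrogate for the microscopy measurement workflow: the needle
#' outline, vascular cylinder, conductive tissue (xylem plus phloem) and
#' xylem are concentric ellipses whose areas equal the needle's measured
#' areas exactly, and each tracheid lumen is an ellipse with semi-axes
#' `d_max/2`, `d_min/2` placed inside the xylem ellipse by dart throwing
#' with rejection (random centre and orientation; a candidate is accepted
#' only if, on a fine occupancy grid, it does not touch a previously placed
#' lumen or the xylem boundary). Deterministic for a fixed `seed`.
#'
#' @param needle One row of a needle table (standard schema).
#' @param tracheids The tracheid rows of that needle (standard schema).
#' @param seed Integer seed for the placement.
#' @param aspect_needle,aspect_vascular Axis ratios of the needle outline
#'   and of the vascular/xylem ellipses. Defaults 2.0 and 1.5.
#' @param max_packing Feasibility bound on total lumen area / xylem area;
#'   requests above it are refused. Default 0.6.
#' @param max_tries Dart throws per tracheid before giving up. Default 4000.
#' @param placement_px_per_um Resolution of the occupancy grid used during
#'   placement (also the guaranteed clearance between lumens: one grid
#'   pixel). Default 4.
#'
#' @return An object of class `section_layout`: tibbles `regions` (region,
#'   semi-axes, exact area) and `tracheids` (id, centre, semi-axes,
#'   orientation), plus the source identifiers.
#' @examples
#' sim <- simulate_needles(sim_config(seed = 3))
#' ndl <- sim$needles[1, ]
#' trs <- dplyr::semi_join(sim$tracheids, ndl, by = c(
#'   "treatment", "canopy", "tree_id", "shoot_id", "needle_id"))
#' lay <- layout_section(ndl, trs, seed = 1)
#' @export
layout_section <- function(needle, tracheids, seed = 1,
                           aspect_needle = 2.0, aspect_vascular = 1.5,
                           max_packing = 0.6, max_tries = 4000,
                           placement_px_per_um = 4) {
  if (nrow(needle) != 1L) abort("`needle` must be a single row.")
  if (nrow(tracheids) < 1L) abort("Need at least one tracheid.")
  a_x <- needle$a_x_um2
  packing <- sum(tracheids$a_lum_um2) / a_x
  if (packing > max_packing) {
    abort(sprintf("Infeasible section: lumen packing %.2f exceeds the %.2f bound.",
                  packing, max_packing))
  }
  regions <- tibble::tibble(
    region = c("needle", "vascular", "conductive", "xylem"),
    area_um2 = c(needle$a_n_mm2 * 1e6, needle$a_v_mm2 * 1e6,
                 a_x + needle$a_p_um2, a_x),
    aspect = c(aspect_needle, rep(aspect_vascular, 3))
  )
  ax <- t(vapply(seq_len(nrow(regions)),
                 function(i) ellipse_axes(regions$area_um2[i], regions$aspect[i]),
                 numeric(2)))
  regions$a <- ax[, 1]
  regions$b <- ax[, 2]
  if (any(diff(regions$area_um2) > 0)) {
    abort("Region areas must nest: needle >= vascular >= conductive >= xylem.")
  }

  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)

  xa <- regions$a[regions$region == "xylem"]
  xb <- regions$b[regions$region == "xylem"]
  grid <- pixel_centers(xa, xb, placement_px_per_um)
  occupied <- matrix(FALSE, nrow = length(grid$x), ncol = length(grid$y))
  margin <- 1 / placement_px_per_um

  ord <- order(tracheids$a_lum_um2, decreasing = TRUE)
  placed <- vector("list", nrow(tracheids))
  for (i in ord) {
    a_t <- tracheids$d_max_um[i] / 2
    b_t <- tracheids$d_min_um[i] / 2
    rc <- a_t + margin
    if (xa - rc <= 0 || xb - rc <= 0) {
      abort(sprintf("Tracheid %s is too large for the xylem ellipse.",
                    tracheids$tracheid_id[i]))
    }
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      u <- runif(1); phi <- runif(1, 0, 2 * pi)
      cx <- (xa - rc) * sqrt(u) * cos(phi)
      cy <- (xb - rc) * sqrt(u) * sin(phi)
      theta <- runif(1, 0, pi)
      cells <- ellipse_cells(grid$x, grid$y, cx, cy,
                             a_t + margin, b_t + margin, theta)
      if (nrow(cells) && !any(occupied[cells])) {
        occupied[cells] <- TRUE
        placed[[i]] <- tibble::tibble(
          tracheid_id = tracheids$tracheid_id[i],
          x = cx, y = cy, a = a_t, b = b_t, theta = theta)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf("Could not place tracheid %s after %d tries (packing %.2f).",
                    tracheids$tracheid_id[i], max_tries, packing))
    }
  }

  structure(list(
    regions = regions[, c("region", "a", "b", "area_um2")],
    tracheids = dplyr::bind_rows(placed),
    ids = needle[, intersect(c(id_cols(), "family"), names(needle))],
    seed = seed, packing = packing
  ), class = "section_layout")
}

#' @export
print.section_layout <- function(x, ...) {
  cat(sprintf("section_layout: %d tracheids, packing %.2f, needle area %.3g um^2\n",
              nrow(x$tracheids), x$packing,
              x$regions$area_um2[x$regions$region == "needle"]))
  invisible(x)
}

#' Rasterize a section layout to a labelled pixel mask
#'
#' Pixel-centre point-in-ellipse rasterization with no anti-aliasing, so the
#' mask is exactly reproducible across platforms. Label codes: 0 background,
#' 1 needle tissue, 2 vascular cylinder, 3 phloem, 4 xylem wall, and
#' `100 + i` for the i-th tracheid lumen.
#'
#' @param layout A [layout_section()] result.
#' @param px_per_um Resolution, pixels per um. Must be positive.
#' @return An object of class `section_raster`: integer label matrix
#'   (x by y) plus pixel-centre coordinates and the resolution.
#' @export
rasterize_section <- function(layout, px_per_um = 4) {
  if (!inherits(layout, "section_layout")) abort("`layout` must be a section_layout.")
  if (px_per_um <= 0) abort("`px_per_um` must be positive.")
  reg <- layout$regions
  na_ <- reg$a[reg$region == "needle"]
  nb_ <- reg$b[reg$region == "needle"]
  grid <- pixel_centers(na_ + 2 / px_per_um, nb_ + 2 / px_per_um, px_per_um)
  labels <- matrix(0L, nrow = length(grid$x), ncol = length(grid$y))
  for (i in seq_len(nrow(reg))) {
    cells <- ellipse_cells(grid$x, grid$y, 0, 0, reg$a[i], reg$b[i], 0)
    labels[cells] <- i  # 1 needle, 2 vascular, 3 conductive, 4 xylem
  }
  for (i in seq_len(nrow(layout$tracheids))) {
    tr <- layout$tracheids[i, ]
    cells <- ellipse_cells(grid$x, grid$y, tr$x, tr$y, tr$a, tr$b, tr$theta)
    labels[cells] <- 100L + i
  }
  structure(list(labels = labels, x = grid$x, y = grid$y,
                 px_per_um = px_per_um, layout = layout),
            class = "section_raster")
}

# caliper diameters of a lumen pixel mask: d_max is the maximum pairwise
# pixel-centre distance, d_min the minimal width over convex-hull edge
# directions; both padded by one pixel for the pixel extent
lumen_calipers <- function(px, py, step) {
  if (length(px) == 1L) return(c(d_max = step, d_min = step))
  pts <- cbind(px, py)
  hull <- pts[grDevices::chull(pts), , drop = FALSE]
  d_max <- sqrt(max(as.matrix(dist(hull))^2))
  n <- nrow(hull)
  widths <- vapply(seq_len(n), function(i) {
    p1 <- hull[i, ]; p2 <- hull[i %% n + 1, ]
    e <- p2 - p1
    len <- sqrt(sum(e^2))
    if (len < 1e-12) return(Inf)
    nrm <- c(-e[2], e[1]) / len
    max(abs((hull[, 1] - p1[1]) * nrm[1] + (hull[, 2] - p1[2]) * nrm[2]))
  }, numeric(1))
  c(d_max = d_max + step, d_min = min(widths) + step)
}

#' Measure areas and lumen diameters from a rasterized section
#'
#' Pixel-count estimates of the section areas and per-lumen calipers,
#' mimicking an image-analysis measurement of a stained cross-section.
#' Areas: needle = all labelled pixels, vascular = labels >= 2, phloem =
#' label 3, xylem = label 4 plus all lumen pixels (lumens lie inside the
#' xylem). Lumens covering fewer than 4 pixels are flagged.
#'
#' @param raster A [rasterize_section()] result.
#' @return A list with one-row tibble `needle` (measured areas in the
#'   standard units) and tibble `tracheids` (measured `d_max_um`,
#'   `d_min_um`, `a_lum_um2`, `flagged`), both carrying the source
#'   identifiers.
#' @export
measure_section <- function(raster) {
  if (!inherits(raster, "section_raster")) abort("`raster` must be a section_raster.")
  L <- raster$labels
  px_area <- (1 / raster$px_per_um)^2
  step <- 1 / raster$px_per_um
  lum <- L >= 100L
  ids <- raster$layout$ids
  needle <- dplyr::bind_cols(ids, tibble::tibble(
    a_n_mm2 = sum(L > 0L) * px_area / 1e6,
    a_v_mm2 = sum(L >= 2L) * px_area / 1e6,
    a_x_um2 = (sum(L == 4L) + sum(lum)) * px_area,
    a_p_um2 = sum(L == 3L) * px_area
  ))
  n_tr <- nrow(raster$layout$tracheids)
  trs <- purrr::map_dfr(seq_len(n_tr), function(i) {
    idx <- which(L == 100L + i, arr.ind = TRUE)
    npx <- nrow(idx)
    if (npx == 0L) {
      return(tibble::tibble(
        tracheid_id = raster$layout$tracheids$tracheid_id[i],
        d_max_um = NA_real_, d_min_um = NA_real_, a_lum_um2 = 0,
        flagged = TRUE))
    }
    cal <- lumen_calipers(raster$x[idx[, 1]], raster$y[idx[, 2]], step)
    tibble::tibble(
      tracheid_id = raster$layout$tracheids$tracheid_id[i],
      d_max_um = unname(cal["d_max"]), d_min_um = unname(cal["d_min"]),
      a_lum_um2 = npx * px_area,
      flagged = npx < 4L)
  })
  if (any(trs$flagged)) {
    warn(sprintf("%d lumen(s) cover fewer than 4 pixels at %.3g px/um; measurements unreliable.",
                 sum(trs$flagged), raster$px_per_um))
  }
  list(needle = needle, tracheids = dplyr::bind_cols(
    ids[rep(1, nrow(trs)), , drop = FALSE], trs))
}

#' Rasterize a layout and re-measure it in one step
#'
#' @inheritParams rasterize_section
#' @return As [measure_section()].
#' @export
rasterize_and_measure <- function(layout, px_per_um = 4) {
  measure_section(rasterize_section(layout, px_per_um))
}

#' Round-trip a set of simulated needles through the section surrogate
#'
#' For each needle: build a layout, rasterize at `px_per_um`, re-measure,
#' and return measurement tables in the standard schemas so the re-measured
#' data can flow through [needle_traits()] exactly like real measurements.
#'
#' @param tracheids,needles Standard measurement tables (e.g. from
#'   [simulate_needles()]); all needles present are processed.
#' @param px_per_um Measurement resolution. Default 4.
#' @param seed Base placement seed; needle i uses `seed + i`.
#' @return A list with re-measured `tracheids` and `needles` tibbles.
#' @export
measure_sections <- function(tracheids, needles, px_per_um = 4, seed = 1) {
  res <- purrr::map(seq_len(nrow(needles)), function(i) {
    ndl <- needles[i, ]
    trs <- dplyr::semi_join(tracheids, ndl, by = id_cols())
    lay <- layout_section(ndl, trs, seed = seed + i)
    rasterize_and_measure(lay, px_per_um)
  })
  list(
    needles = purrr::map_dfr(res, "needle") |>
      dplyr::select(dplyr::all_of(needle_schema())),
    tracheids = purrr::map_dfr(res, "tracheids") |>
      dplyr::select(dplyr::all_of(c(tracheid_schema(), "flagged")))
  )
}

#' Export a labelled section mask as a PNG image
#'
#' One gray level per region class (background 0, needle tissue, vascular,
#' phloem, xylem wall, lumens brightest).
#'
#' @param raster A [rasterize_section()] result.
#' @param path Output PNG path.
#' @return Invisibly, `path`.
#' @export
write_section_png <- function(raster, path) {
  L <- raster$labels
  g <- matrix(0, nrow = nrow(L), ncol = ncol(L))
  g[L == 1L] <- 60 / 255
  g[L == 2L] <- 110 / 255
  g[L == 3L] <- 160 / 255
  g[L == 4L] <- 200 / 255
  g[L >= 100L] <- 1
  png::writePNG(t(g)[rev(seq_len(ncol(L))), , drop = FALSE], path)
  invisible(path)
}
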
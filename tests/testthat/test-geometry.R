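test_that("a large circular lumen is measured to sub-percent accuracy", {
  # one circular tracheid of radius 12.5 um -> 50 px at 4 px/um
  d <- 25
  trs <- tiny_tracheids(d_max = d, d_min = d)
  ndl <- tiny_needles(a_n_mm2 = 0.02, a_v_mm2 = 0.005, a_x_um2 = 2000,
                      a_p_um2 = 1000)
  lay <- layout_section(ndl, trs, seed = 1)
  meas <- rasterize_and_measure(lay, px_per_um = 4)
  true_area <- pi * (d / 2)^2
  expect_lt(abs(meas$tracheids$a_lum_um2 - true_area) / true_area, 0.01)
  expect_false(meas$tracheids$flagged)
  expect_equal(meas$tracheids$d_max_um, d, tolerance = 0.03)
  expect_equal(meas$tracheids$d_min_um, d, tolerance = 0.03)
})

test_that("region ellipse areas match the source needle exactly", {
  lay <- layout_section(tiny_needles(), tiny_tracheids(), seed = 1)
  areas <- setNames(lay$regions$area_um2, lay$regions$region)
  expect_equal(unname(areas["needle"]), 0.35e6)
  expect_equal(unname(areas["vascular"]), 0.019e6)
  expect_equal(unname(areas["xylem"]), 930)
  expect_equal(unname(areas["conductive"]), 930 + 1270)
  # analytic pi*a*b agrees with the stored area
  expect_equal(pi * lay$regions$a * lay$regions$b, lay$regions$area_um2)
})

test_that("excessive packing requests are refused", {
  d <- 30
  trs <- tiny_tracheids(d_max = d, d_min = d)
  ndl <- tiny_needles(a_n_mm2 = 0.02, a_v_mm2 = 0.005, a_x_um2 = 786,
                      a_p_um2 = 500)  # packing ~0.9
  expect_error(layout_section(ndl, trs), "packing")
})

test_that("placement is deterministic and lumens never overlap", {
  sim <- simulate_needles(sim_config(seed = 3))
  ndl <- sim$needles[sim$needles$canopy == "sun" &
                     sim$needles$treatment == "control", ][1, ]
  trs <- dplyr::semi_join(sim$tracheids, ndl,
                          by = c("treatment", "canopy", "tree_id",
                                 "shoot_id", "needle_id"))
  lay1 <- layout_section(ndl, trs, seed = 7)
  lay2 <- layout_section(ndl, trs, seed = 7)
  expect_identical(lay1$tracheids, lay2$tracheids)
  # independent overlap check: dense boundary/interior samples of each
  # ellipse must fall outside every other ellipse
  phi <- seq(0, 2 * pi, length.out = 360)
  pts <- lapply(seq_len(nrow(lay1$tracheids)), function(i) {
    tr <- lay1$tracheids[i, ]
    lapply(c(1, 0.6, 0.2), function(f) {
      cbind(tr$x + f * tr$a * cos(phi) * cos(tr$theta) -
              f * tr$b * sin(phi) * sin(tr$theta),
            tr$y + f * tr$a * cos(phi) * sin(tr$theta) +
              f * tr$b * sin(phi) * cos(tr$theta))
    }) |> (\(l) do.call(rbind, l))()
  })
  inside <- function(p, tr) {
    dx <- p[, 1] - tr$x; dy <- p[, 2] - tr$y
    u <- (dx * cos(tr$theta) + dy * sin(tr$theta)) / tr$a
    v <- (-dx * sin(tr$theta) + dy * cos(tr$theta)) / tr$b
    u^2 + v^2 < 1
  }
  for (i in seq_along(pts)) {
    for (j in seq_along(pts)) {
      if (i != j) expect_false(any(inside(pts[[i]], lay1$tracheids[j, ])))
    }
  }
})

test_that("refining the resolution does not worsen section-area error", {
  lay <- layout_section(tiny_needles(), tiny_tracheids(), seed = 2)
  err <- function(px) {
    m <- rasterize_and_measure(lay, px_per_um = px)$needle
    truth <- c(0.35e6, 0.019e6, 930, 1270)
    got <- c(m$a_n_mm2 * 1e6, m$a_v_mm2 * 1e6, m$a_x_um2, m$a_p_um2)
    max(abs(got - truth) / truth)
  }
  e1 <- err(1); e2 <- err(2); e4 <- err(4)
  expect_lte(e4, e2 + 1e-12)
  expect_lte(e2, e1 + 1e-12)
})

test_that("undersampled lumens are flagged with a warning", {
  trs <- tiny_tracheids(d_max = 3, d_min = 2)
  ndl <- tiny_needles(a_n_mm2 = 0.02, a_v_mm2 = 0.005, a_x_um2 = 500,
                      a_p_um2 = 300)
  lay <- layout_section(ndl, trs, seed = 1)
  expect_warning(m <- rasterize_and_measure(lay, px_per_um = 0.5), "4 pixels")
  expect_true(m$tracheids$flagged)
})

test_that("re-measured traits rank-correlate with the true traits", {
  sim <- simulate_needles(sim_config(trees_per_plot = 1, shoots_per_tree = 2,
                                     needles_per_shoot = 2, seed = 9))
  keep <- sim$needles  # all 16 needles of the mini 2 x 2 design
  trs <- dplyr::semi_join(sim$tracheids, keep,
                          by = c("treatment", "canopy", "tree_id",
                                 "shoot_id", "needle_id"))
  meas <- measure_sections(trs, keep, px_per_um = 4, seed = 100)
  true_traits <- needle_traits(trs, keep)
  meas_traits <- needle_traits(
    dplyr::select(meas$tracheids, -dplyr::any_of("flagged")), meas$needles)
  key <- c("treatment", "canopy", "tree_id", "shoot_id", "needle_id")
  cmp <- dplyr::inner_join(true_traits, meas_traits, by = key,
                           suffix = c("_true", "_meas"))
  expect_equal(nrow(cmp), nrow(keep))
  for (trait in c("A_n", "A_x", "N_lum", "k_th", "d_max")) {
    rho <- cor(cmp[[paste0(trait, "_true")]], cmp[[paste0(trait, "_meas")]],
               method = "spearman")
    expect_gte(rho, 0.95)
  }
})

test_that("PNG export writes a readable labelled mask", {
  lay <- layout_section(tiny_needles(), tiny_tracheids(), seed = 1)
  ras <- rasterize_section(lay, px_per_um = 1)
  path <- withr::local_tempfile(fileext = ".png")
  write_section_png(ras, path)
  img <- png::readPNG(path)
  expect_equal(dim(img), c(ncol(ras$labels), nrow(ras$labels)))
  expect_true(any(img == 1))  # lumens present at the brightest level
})
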
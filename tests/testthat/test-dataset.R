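test_that("padding repeats boundary postures with zero velocity and seeded onsets", {
  m <- matrix(stats::runif(25 * 100, 0.1, 0.3), 25, 100)
  v <- muscle_velocities(m, 0.015)
  e <- matrix(stats::rnorm(300), 100, 3)

  set.seed(5)
  pj <- pad_and_jitter(m, v, e, T_out = 320)
  expect_equal(ncol(pj$m), 320)
  expect_gte(pj$onset, 0); expect_lte(pj$onset, 220)
  pre <- seq_len(pj$onset)
  post <- (pj$onset + 101):320
  if (length(pre)) {
    expect_true(all(pj$m[, pre] == m[, 1]))
    expect_true(all(pj$v[, pre] == 0))
    expect_true(all(pj$e[pre, ] == rep(e[1, ], each = length(pre))))
  }
  expect_true(all(pj$v[, post] == 0))
  expect_true(all(pj$m[, post] == m[, 100]))
  expect_equal(pj$m[, pj$onset + 1:100], m)

  set.seed(5)
  pj2 <- pad_and_jitter(m, v, e, T_out = 320)
  expect_identical(pj2$onset, pj$onset)

  exact <- pad_and_jitter(m, v, e, T_out = 100)
  expect_identical(exact$onset, 0L)
  expect_identical(exact$m, m)
  expect_error(pad_and_jitter(m, v, e, T_out = 99), class = "pt_shape_error")
})

test_that("jerk filtering scores smooth and discontinuous trajectories correctly", {
  dt <- 0.015
  tgrid <- (0:99) * dt
  const <- structure(list(q = matrix(1, 100, 4), dt = dt),
                     class = "joint_trajectory")
  r <- joint_jerk_filter(const)
  expect_true(r$pass); expect_equal(r$score, 0)

  quad <- structure(list(q = cbind(tgrid^2, 2 * tgrid^2, 0.5 * tgrid^2,
                                   tgrid^2), dt = dt),
                    class = "joint_trajectory")
  r2 <- joint_jerk_filter(quad)
  expect_true(r2$pass)
  expect_equal(r2$score, 0, tolerance = 1e-9)

  blip <- matrix(0, 100, 4); blip[50, 1] <- 0.01
  r3 <- joint_jerk_filter(blip, dt = dt)
  # a single-frame discontinuity of amplitude a scores a * 8 / dt^2
  expect_false(r3$pass)
  expect_equal(r3$score, 0.01 * 8 / dt^2, tolerance = 1e-6)
  expect_error(joint_jerk_filter(matrix(0, 3, 4), dt = dt),
               class = "pt_shape_error")
})

test_that("balanced selection keeps the smallest muscle jerk per class", {
  set.seed(8)
  cand <- data.frame(id = 1:120,
                     label = rep(character_classes()[1:4], each = 30),
                     muscle_jerk = stats::runif(120))
  keep <- select_balanced(cand, 40)
  expect_equal(unname(table(keep$label)[character_classes()[1:4]]),
               rep(10L, 4), ignore_attr = TRUE)
  for (cl in character_classes()[1:4]) {
    kept <- keep$muscle_jerk[keep$label == cl]
    dropped <- setdiff(cand$muscle_jerk[cand$label == cl], kept)
    expect_lte(max(kept), min(dropped))
  }
  expect_error(select_balanced(cand[1:25, ], 40),
               class = "pt_insufficient_candidates")
})

test_that("stratified splits honor the 72-8-20 ratio deterministically", {
  labels <- rep(character_classes(), each = 50)
  sp <- split_dataset(labels, seed = 7)
  expect_equal(as.vector(table(sp)), c(720, 80, 200))
  sp2 <- split_dataset(labels, seed = 7)
  expect_identical(sp, sp2)
  for (cl in character_classes()) {
    frac <- mean(sp[labels == cl] == "test")
    expect_lte(abs(frac - 0.2), 1 / 50)
  }
  expect_error(split_dataset(labels, ratios = c(0.5, 0.5, 0.5)),
               class = "pt_config_error")
})

test_that("the dataset container round-trips and tracks its config hash", {
  ds <- tiny_dataset()
  path <- withr::local_tempfile(fileext = ".rds")
  write_dataset(ds, path)
  expect_true(file.exists(paste0(path, ".manifest.json")))
  back <- read_dataset(path)
  expect_identical(back$inputs, ds$inputs)
  expect_identical(back$manifest, ds$manifest)
  expect_identical(back$split, ds$split)
  expect_identical(back$config$hash, ds$config$hash)

  # version gate
  payload <- readRDS(path)
  payload$.format_version <- 99L
  saveRDS(payload, path)
  expect_error(read_dataset(path), class = "pt_format_error")

  # changing any generator parameter changes the hash
  cfg2 <- ds$config
  cfg3 <- dataset_config(n_samples = ds$config$n_samples + 20)
  expect_false(identical(cfg2$hash, cfg3$hash))
})

test_that("generated datasets are balanced, jerk-filtered, and reproducible", {
  ds <- tiny_dataset()
  expect_equal(length(unique(table(ds$labels))), 1L)
  expect_true(all(ds$manifest$joint_jerk < ds$config$jerk_threshold))
  expect_false(anyNA(ds$inputs))
  # position+velocity targets carry 6 channels scaled to the train range
  pv <- tdt_pv_targets(ds)
  expect_equal(dim(pv$targets)[3], 6)
  tr <- which(ds$split == "train")
  expect_gte(min(pv$targets[tr, , ]), 0)
  expect_lte(max(pv$targets[tr, , ]), 1)
})
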
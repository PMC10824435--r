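test_that("t statistic and quality measure match hand values", {
  expect_equal(t_statistic(c(-1, 1, -1, 1)), 0)
  expect_equal(t_statistic(c(1, 2, 3)), 2 * sqrt(3), tolerance = 1e-10)
  expect_equal(t_statistic(c(1, 2, 3)), 3.4641, tolerance = 1e-4)
  expect_error(t_statistic(c(1)), "fewer than 2")
  expect_error(t_statistic(c(2, 2, 2)), "constant")

  expect_equal(quality_measure(c(1, 2, 3), "high"), 3.4641, tolerance = 1e-4)
  expect_equal(quality_measure(c(1, 2, 3), "low"), -3.4641, tolerance = 1e-4)
  expect_equal(quality_measure(c(-1, -2, -3), "low"), 3.4641, tolerance = 1e-4)
})

test_that("quality is scale-free and direction-symmetric", {
  set.seed(42)
  for (i in 1:20) {
    v <- rnorm(sample(3:30, 1), mean = runif(1, -1, 1))
    k <- runif(1, 0.1, 50)
    expect_equal(quality_measure(k * v, "high"), quality_measure(v, "high"),
                 tolerance = 1e-10)
    expect_equal(quality_measure(v, "low"), quality_measure(-v, "high"),
                 tolerance = 1e-12)
  }
})

test_that("refinement counts follow the discretization rules", {
  rec <- tibble::tibble(.key = as.character(1:8),
                        K_soil = c(1, 2, 3, 4, 5, 6, 7, 8))
  # one numeric attribute with two bins: a median split, <= and >
  cands <- refine(list(), rec, "K_soil", n_bins = 2)
  expect_length(cands, 2)
  kinds <- vapply(cands, function(d) d[[1]]$kind, character(1))
  expect_setequal(kinds, c("le", "gt"))

  # one categorical attribute with three observed levels: 6 candidates
  rec2 <- tibble::tibble(.key = as.character(1:9),
                         Dryness = rep(c("dry", "average", "wet"), 3))
  cands2 <- refine(list(), rec2, "Dryness", n_bins = 6)
  expect_length(cands2, 6)
})

test_that("refinement never loosens an existing numeric bound", {
  rec <- records12()
  base <- list(egmine:::new_condition("K_soil", "le", 190))
  for (cand in refine(base, rec, c("K_soil", "Mg_soil"), n_bins = 4)) {
    les <- Filter(function(cd) cd$attribute == "K_soil" && cd$kind == "le",
                  cand)
    expect_lte(length(les), 1)
    if (length(les)) expect_lte(les[[1]]$value, 190)
  }
})

test_that("membership matches a brute-force filter on a known fixture", {
  rec <- records12()
  tg <- targets12()
  desc <- list(
    egmine:::new_condition("K_soil", "le", 230),
    egmine:::new_condition("Dryness", "neq", "wet")
  )
  row <- egmine:::evaluate_desc(desc, rec, tg, "high")
  manual <- rec$.key[rec$K_soil <= 230 & rec$Dryness != "wet"]
  expect_setequal(row$members[[1]], manual)
  vals <- tg[rec$.key %in% manual]
  expect_equal(row$n, length(vals))
  expect_equal(row$mean, mean(vals))
  expect_equal(row$t, mean(vals) * sqrt(length(vals)) / sd(vals))

  # empty description covers everything; impossible one scores -Inf
  all_row <- egmine:::evaluate_desc(list(), rec, tg, "high")
  expect_equal(all_row$n, 12)
  expect_equal(all_row$mean, mean(tg))
  none <- egmine:::evaluate_desc(
    list(egmine:::new_condition("K_soil", "gt", 1e6)), rec, tg, "high"
  )
  expect_identical(none$quality, -Inf)
})

test_that("beam search isolates a separable binary descriptor", {
  rec <- tibble::tibble(
    .key = as.character(1:10),
    Nutrient_content = rep(c("rich", "poor"), each = 5)
  )
  tg <- c(rep(1, 5), rep(-1, 5)) + seq(-0.1, 0.1, length.out = 10)
  out <- beam_search(rec, tg, "Nutrient_content", direction = "high",
                     beam_width = 5, depth = 1)
  # the +1 side wins (reachable as == 'rich' or the equivalent != 'poor')
  expect_setequal(out$members[[1]], as.character(1:5))
  expect_equal(out$n[1], 5)
  expect_true("Nutrient_content == 'rich'" %in%
                out$description[out$n == 5 & out$quality == out$quality[1]])
})

test_that("infinite beam width equals exhaustive enumeration", {
  rec <- records12()
  tg <- targets12()
  descr <- c("K_soil", "Mg_soil", "Dryness")
  got <- beam_search(rec, tg, descr, direction = "high",
                     beam_width = Inf, depth = 2, n_bins = 3)
  oracle <- enumerate_descriptions(rec, tg, descr, depth = 2, n_bins = 3,
                                   direction = "high")
  got_f <- got[is.finite(got$quality), ]
  or_f <- oracle[is.finite(oracle$quality), ]
  expect_setequal(
    unique(paste(got_f$description, got_f$n, round(got_f$quality, 6))),
    unique(paste(or_f$description, or_f$n, round(or_f$quality, 6)))
  )
})

test_that("narrow beams never beat the exhaustive beam", {
  rec <- records12()
  tg <- targets12()
  descr <- c("K_soil", "Mg_soil", "Dryness")
  full <- beam_search(rec, tg, descr, direction = "high",
                      beam_width = Inf, depth = 2, n_bins = 3)
  narrow <- beam_search(rec, tg, descr, direction = "high",
                        beam_width = 1, depth = 2, n_bins = 3)
  expect_lte(narrow$quality[1], full$quality[1] + 1e-12)
  # and every narrow-beam subgroup also exists in the exhaustive run
  expect_true(all(narrow$description %in% full$description))
})

test_that("reported statistics recompute exactly from the member lists", {
  rec <- records12()
  tg <- targets12()
  out <- beam_search(rec, tg, c("K_soil", "Dryness"), direction = "low",
                     beam_width = 10, depth = 2, n_bins = 4)
  out <- out[is.finite(out$quality), ]
  for (i in seq_len(nrow(out))) {
    vals <- tg[match(out$members[[i]], rec$.key)]
    expect_equal(out$mean[i], mean(vals))
    expect_equal(out$sd[i], sd(vals))
    expect_equal(out$quality[i], -mean(vals) * sqrt(length(vals)) / sd(vals))
  }
})

test_that("mining joins targets by field and year", {
  sim <- tiny_sim(seed = 19, n_per_year = 20)
  p <- true_params_std(sim$config, sim$data$time_scale)
  eb <- eb_random_effects(p, sim$data)
  out <- mine_subgroups(sim$data, eb, target = "a", direction = "high",
                        beam_width = 5, depth = 1, n_bins = 3)
  expect_true(all(out$target == "a"))
  expect_true(all(out$depth == 1))
  # stats of the best subgroup recompute from eb
  best <- out[1, ]
  keys <- paste(eb$field_id, eb$year, sep = "|")
  vals <- eb$a[match(best$members[[1]], keys)]
  expect_equal(best$mean, mean(vals))
})
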
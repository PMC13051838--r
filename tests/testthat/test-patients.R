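test_that("joint distribution factors incidence and stage-given-type", {
  # single cell: marginals pass through
  inc <- tibble::tibble(zcta_id = "z", cancer_type = "t", mean_annual_cases = 100)
  st <- tibble::tibble(cancer_type = "t", stage = c("early", "late"),
                       prob = c(0.6, 0.4))
  d <- build_joint_distribution(inc, st)
  expect_equal(attr(d, "lambda"), 100)
  expect_equal(sort(d$prob), c(0.4, 0.6))

  # two ZCTAs 30/70, stages 0.5/0.5 -> cells 0.15/0.15/0.35/0.35
  inc2 <- tibble::tibble(zcta_id = c("a", "b"), cancer_type = "t",
                         mean_annual_cases = c(30, 70))
  st2 <- tibble::tibble(cancer_type = "t", stage = c("s1", "s2"),
                        prob = c(0.5, 0.5))
  d2 <- build_joint_distribution(inc2, st2)
  expect_equal(sort(d2$prob), c(0.15, 0.15, 0.35, 0.35))
  expect_equal(sum(d2$prob), 1)

  # normalization holds for arbitrary generated tables
  inputs <- generate_catchment(synthetic_spec(n_zctas = 9, seed = 8))
  d3 <- build_joint_distribution(inputs$incidence, inputs$stages)
  expect_equal(sum(d3$prob), 1, tolerance = 1e-12)

  expect_error(
    build_joint_distribution(inc, st[st$cancer_type == "none", ]),
    "missing from stage table"
  )
})

test_that("annual cohort size is Poisson around lambda", {
  inc <- tibble::tibble(zcta_id = "z", cancer_type = "t", mean_annual_cases = 183)
  st <- tibble::tibble(cancer_type = "t", stage = "s", prob = 1)
  d <- build_joint_distribution(inc, st)
  set.seed(183)
  sizes <- replicate(5000, nrow(sample_annual_cohort(d)))
  expect_lt(abs(mean(sizes) - 183), 1)
  expect_gt(stats::sd(sizes), 11)
  expect_lt(stats::sd(sizes), 16)

  expect_equal(nrow(sample_annual_cohort(d, fixed_n = TRUE)), 183)
})

test_that("degenerate distribution and fixed seeds behave deterministically", {
  inc <- tibble::tibble(zcta_id = "z", cancer_type = "t", mean_annual_cases = 20)
  st <- tibble::tibble(cancer_type = "t", stage = "only", prob = 1)
  d <- build_joint_distribution(inc, st)
  set.seed(1)
  co <- sample_annual_cohort(d)
  expect_true(all(co$zcta_id == "z" & co$cancer_type == "t" & co$stage == "only"))
  expect_equal(co$order_index, seq_len(nrow(co)) - 1L)

  set.seed(7); a <- sample_annual_cohort(d)
  set.seed(7); b <- sample_annual_cohort(d)
  expect_identical(a, b)
})

test_that("cohort cell frequencies match the joint distribution", {
  inputs <- generate_catchment(synthetic_spec(n_zctas = 4, total_incidence = 50000,
                                              seed = 10))
  d <- build_joint_distribution(inputs$incidence, inputs$stages)
  set.seed(123)
  co <- sample_annual_cohort(d, fixed_n = TRUE)
  obs <- co |>
    dplyr::count(zcta_id, cancer_type, stage) |>
    dplyr::right_join(d, by = c("zcta_id", "cancer_type", "stage")) |>
    dplyr::mutate(n = dplyr::coalesce(n, 0L))
  gof <- suppressWarnings(stats::chisq.test(obs$n, p = obs$prob))
  expect_gt(gof$p.value, 0.01)
})

test_that("within a cancer type, sampled ZCTA and stage are independent", {
  inc <- tidyr::expand_grid(zcta_id = c("a", "b"), cancer_type = c("t1", "t2")) |>
    dplyr::mutate(mean_annual_cases = 300 * c(60, 10, 20, 40))
  st <- tidyr::expand_grid(cancer_type = c("t1", "t2"), stage = c("early", "late")) |>
    dplyr::mutate(prob = c(0.7, 0.3, 0.2, 0.8))
  d <- build_joint_distribution(inc, st)
  set.seed(5)
  co <- sample_annual_cohort(d, fixed_n = TRUE)
  for (tp in c("t1", "t2")) {
    sub <- co[co$cancer_type == tp, ]
    r <- stats::cor(sub$zcta_id == "a", sub$stage == "late")
    expect_lt(abs(r), 4 / sqrt(nrow(sub)))  # ~4 standard errors of zero
  }
})

test_that("specialty demand draws are Bernoulli with the table's probabilities", {
  inc <- tibble::tibble(zcta_id = "z", cancer_type = "t", mean_annual_cases = 10000)
  st <- tibble::tibble(cancer_type = "t", stage = "s", prob = 1)
  d <- build_joint_distribution(inc, st)
  set.seed(2)
  co <- sample_annual_cohort(d, fixed_n = TRUE)

  dem <- function(p) tibble::tibble(cancer_type = "t", stage = "s",
                                    specialty = "medical", prob = p)
  expect_true(all(draw_specialty_demand(co, dem(1), "medical")$demand_medical))
  expect_false(any(draw_specialty_demand(co, dem(0), "medical")$demand_medical))
  frac <- mean(draw_specialty_demand(co, dem(0.5), "medical")$demand_medical)
  expect_lt(abs(frac - 0.5), 0.015)

  expect_error(draw_specialty_demand(co, dem(0.5), "radiation"), "no demand rows")
  co2 <- co; co2$stage <- "unseen"
  expect_error(draw_specialty_demand(co2, dem(0.5), "medical"), "does not cover")
})
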
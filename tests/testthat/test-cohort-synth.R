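test_that("default schema matches the cohort's reported descriptives", {
  sch <- default_schema()
  nm <- vapply(sch, `[[`, "", "name")
  expect_length(sch, 17)
  expect_false(anyDuplicated(nm) > 0)
  expect_identical(nm, c("Sex", "Age", "Marital", "Social", "NP1", "NP2",
                         "NP3", "BMI", "HTN", "Glucose", "Insulin",
                         "CholesT", "TAG", "HOMA", "Depre", "Anxiety",
                         "Stress"))
  byname <- stats::setNames(sch, nm)
  expect_equal(byname$Glucose$mean, 147.80)
  expect_equal(byname$Glucose$sd, 52.43)
  expect_equal(byname$Insulin$mean, 2.54)
  expect_equal(byname$Age$mean, 20.8)
  expect_equal(byname$Age$sd, 2.6)
  expect_equal(byname$HTN$category_probs, c(140, 48) / 188)
  expect_equal(round(byname$HTN$category_probs, 3), c(0.745, 0.255))
  expect_equal(byname$Sex$category_probs[2], 81 / 188)
  expect_equal(byname$Marital$category_probs, c(148, 35, 5) / 188)
  expect_equal(byname$Social$category_probs, c(71, 62, 55) / 188)
  for (s in sch) {
    if (s$vartype == "continuous") {
      expect_gt(s$sd, 0)
    } else {
      expect_equal(sum(s$category_probs), 1, tolerance = 1e-12)
    }
  }
  blocks <- vapply(sch, `[[`, "", "block")
  expect_setequal(nm[blocks == "metabolic_glycemic"],
                  c("Insulin", "Glucose", "HOMA"))
  expect_setequal(nm[blocks == "lipid"], c("CholesT", "TAG"))
})

test_that("generation is seed-deterministic and respects codings", {
  cfg <- generator_config(n = 120, seed = 11)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_false(identical(a, generate_cohort(generator_config(n = 120, seed = 12))))

  v <- a$values
  expect_false(anyNA(v))
  expect_true(all(v[, "Sex"] %in% 0:1))
  expect_true(all(v[, "HTN"] %in% 0:1))
  expect_true(all(v[, "Marital"] %in% 0:2))
  expect_true(all(v[, "Social"] %in% 0:2))
  # formula mode: HOMA column is the deterministic index
  expect_equal(v[, "HOMA"], homa_ir(v[, "Insulin"], v[, "Glucose"]),
               tolerance = 1e-9)
})

test_that("sampled HOMA mode keeps the latent draw instead of the formula", {
  cfg <- generator_config(n = 400, seed = 3, homa_mode = "sampled")
  v <- generate_cohort(cfg)$values
  expect_gt(max(abs(v[, "HOMA"] - homa_ir(v[, "Insulin"], v[, "Glucose"]))), 1)
  expect_equal(mean(v[, "HOMA"]), 10.69, tolerance = 0.05 * 10.69)
})

test_that("large samples recover the marginals and the latent correlation", {
  cfg <- generator_config(n = 1e5, within_block_rho = 0.6,
                          between_block_rho = 0.05, seed = 2024)
  cohort <- generate_cohort(cfg)
  v <- cohort$values
  for (s in cohort$schema) {
    x <- v[, s$name]
    if (s$vartype == "continuous") {
      if (s$name == "HOMA") next  # overwritten by the formula
      if (abs(s$mean) < 1e-12) {
        expect_lt(abs(mean(x)), 0.02)
      } else {
        expect_lt(abs(mean(x) - s$mean) / abs(s$mean), 0.02)
      }
      expect_lt(abs(stats::sd(x) - s$sd) / s$sd, 0.02)
    } else {
      freq <- tabulate(x + 1, nbins = length(s$category_probs)) / length(x)
      expect_true(all(abs(freq - s$category_probs) < 0.01))
    }
  }
  sch <- stats::setNames(cohort$schema,
                         vapply(cohort$schema, `[[`, "", "name"))
  target <- oracle_copula_cor(0.6, sch$Insulin, sch$Glucose)
  expect_lt(abs(stats::cor(v[, "Insulin"], v[, "Glucose"]) - target), 0.05)
})

test_that("cross-block partial correlations vanish when between-rho is 0", {
  cfg <- generator_config(n = 1e4, within_block_rho = 0.6,
                          between_block_rho = 0, seed = 5)
  cohort <- generate_cohort(cfg)
  pc <- partial_correlations(cohort)
  nm <- vapply(cohort$schema, `[[`, "", "name")
  blocks <- stats::setNames(vapply(cohort$schema, `[[`, "", "block"), nm)
  cont <- stats::setNames(
    vapply(cohort$schema, `[[`, "", "vartype") == "continuous", nm)
  labs <- pc$labels
  vals <- c()
  for (i in seq_along(labs)[-length(labs)]) {
    for (j in (i + 1):length(labs)) {
      if (blocks[labs[i]] != blocks[labs[j]] &&
          cont[labs[i]] && cont[labs[j]] &&
          !(labs[i] %in% c("HOMA")) && !(labs[j] %in% c("HOMA"))) {
        vals <- c(vals, pc$rp[i, j])
      }
    }
  }
  expect_lt(mean(abs(vals)), 0.05)
})

test_that("a non-positive-definite latent matrix fails loudly", {
  expect_error(
    generate_cohort(generator_config(n = 100, within_block_rho = -0.2,
                                     between_block_rho = 0)),
    "positive definite"
  )
  expect_error(generator_config(n = 10), ">= 20")
  expect_error(generator_config(within_block_rho = 1.2), "rho")
})

test_that("cohort CSV and schema YAML round-trip", {
  cfg <- generator_config(n = 40, seed = 8)
  cohort <- generate_cohort(cfg)
  csv <- withr::local_tempfile(fileext = ".csv")
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_cohort_csv(cohort, csv, yml)
  back <- read_cohort_csv(csv)
  expect_equal(back$values, cohort$values, tolerance = 1e-12)
  expect_identical(back$id, cohort$id)
  sch <- read_schema_yaml(yml)
  expect_equal(vapply(sch, `[[`, "", "name"),
               vapply(cohort$schema, `[[`, "", "name"))
  expect_equal(sch[[10]]$mean, 147.80)

  # malformed input: a missing column is named in the error
  df <- utils::read.csv(csv)
  df$Glucose <- NULL
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, bad, row.names = FALSE)
  expect_error(read_cohort_csv(bad), "Glucose")
})
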
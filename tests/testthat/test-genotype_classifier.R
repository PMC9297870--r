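profile_row <- function(e, t1, t2, m, id = "x") {
  data.frame(individual_id = id, population_id = "p",
             epsps_cn = e, type1_cn = t1, type2_cn = t2, mge_cn = m)
}

test_that("the decision cascade reproduces the surveyed worked examples", {
  cases <- list(
    list(cn = c(10.3, 11.9, 3.9, 22.5), g = "A", flag = ""),
    list(cn = c(15.4, 0, 0, 25.8),     g = "B", flag = ""),
    list(cn = c(3.6, 0, 0, 5.2),       g = "C", flag = ""),
    list(cn = c(0.8, 0, 0, 3.5),       g = "S", flag = ""),
    list(cn = c(5.9, 5.9, 3.8, 3.2),   g = "A", flag = "atypical_low_MGE_A"),
    list(cn = c(1.0, 0, 0, 56.0),      g = "S", flag = "high_MGE_susceptible"))
  for (cs in cases) {
    call <- classify_profiles(profile_row(cs$cn[1], cs$cn[2], cs$cn[3], cs$cn[4]))
    expect_equal(as.character(call$genotype), cs$g)
    expect_equal(call$flags, cs$flag)
  }
})

test_that("threshold boundaries are strict where specified", {
  # EPSPS exactly at 1.4 is not "increased"
  expect_equal(as.character(classify_profiles(profile_row(1.4, 0, 0, 4))$genotype), "S")
  expect_equal(as.character(classify_profiles(profile_row(1.41, 0, 0, 4))$genotype), "C")
  # MGE exactly 10 is "increased"
  expect_equal(as.character(classify_profiles(profile_row(5, 0, 0, 10))$genotype), "B")
  expect_equal(as.character(classify_profiles(profile_row(5, 0, 0, 9.99))$genotype), "C")
})

test_that("discordant repeat markers fall through to the MGE rule with a flag", {
  lo <- classify_profiles(profile_row(5, 2, 0, 4))
  expect_equal(as.character(lo$genotype), "C")
  expect_match(lo$flags, "discordant_repeat_markers")
  hi <- classify_profiles(profile_row(5, 0, 2, 15))
  expect_equal(as.character(hi$genotype), "B")
  expect_match(hi$flags, "discordant_repeat_markers")
  expect_error(classify_profiles(profile_row(-1, 0, 0, 4)), "negative")
})

test_that("the cascade is total and threshold-monotone", {
  set.seed(23)
  prof <- data.frame(individual_id = paste0("i", 1:300), population_id = "p",
                     epsps_cn = runif(300, 0, 20),
                     type1_cn = sample(c(0, runif(300, 0, 15)), 300, TRUE),
                     type2_cn = sample(c(0, runif(300, 0, 6)), 300, TRUE),
                     mge_cn = runif(300, 0, 40))
  g1 <- classify_profiles(prof, dup_thresholds(epsps_increased = 1.4))$genotype
  expect_false(anyNA(g1))
  g2 <- classify_profiles(prof, dup_thresholds(epsps_increased = 2.5))$genotype
  expect_true(all(g2[g1 == "S"] == "S"))  # raising the cutoff never un-calls S
})

test_that("population mean profiles from the survey reproduce printed modal genotypes", {
  tab <- utils::read.csv(system.file("extdata", "survey_population_means.csv",
                                     package = "dupepi"))
  prof <- data.frame(individual_id = tab$row_id, population_id = tab$population_id,
                     epsps_cn = tab$epsps_mean, type1_cn = tab$type1_mean,
                     type2_cn = tab$type2_mean, mge_cn = tab$mge_mean)
  calls <- classify_profiles(prof)
  pure <- tab$p_A == 1 | tab$p_B == 1 | tab$p_C == 1 | tab$p_S == 1
  modal <- c("A", "B", "C", "S")[apply(tab[, c("p_A", "p_B", "p_C", "p_S")], 1,
                                       which.max)]
  # The "Wild" row prints all-C proportions alongside a mean MGE of 16.4,
  # which cannot arise from three individuals each below the MGE threshold;
  # the row is internally inconsistent and excluded (see decisions ledger).
  ok <- pure & tab$population_id != "Wild"
  expect_true(all(as.character(calls$genotype)[ok] == modal[ok]))
  wild <- calls$genotype[tab$population_id == "Wild"]
  expect_equal(as.character(wild), "B")
})

test_that("population summaries count calls and propagate metadata", {
  prof <- rbind(profile_row(1, 0, 0, 4, "a"), profile_row(1, 0, 0, 5, "b"),
                profile_row(15, 0, 0, 20, "c"))
  calls <- classify_profiles(prof)
  meta <- data.frame(population_id = "p", region = "Northern Plains")
  s <- summarize_populations(prof, calls, meta)
  expect_equal(unlist(s[, c("p_A", "p_B", "p_C", "p_S")], use.names = FALSE),
               c(0, 1 / 3, 0, 2 / 3))
  expect_equal(s$epsps_se, stats::sd(c(1, 1, 15)) / sqrt(3))

  same <- do.call(rbind, lapply(1:5, function(i)
    profile_row(10.3, 11.9, 3.9, 22.5, paste0("i", i))))
  s2 <- summarize_populations(same, classify_profiles(same), meta)
  expect_equal(s2$p_A, 1.0)
  expect_equal(s2$epsps_se, 0)

  one <- profile_row(2, 0, 0, 4, "solo")
  s3 <- summarize_populations(one, classify_profiles(one), meta)
  expect_true(is.na(s3$epsps_se))  # SE undefined at n = 1

  expect_error(summarize_populations(prof, calls,
                                     data.frame(population_id = "q",
                                                region = "Northern Plains")),
               "absent from metadata")
})

test_that("regional pooling is weighted by sample size", {
  prof <- rbind(
    do.call(rbind, lapply(1:2, function(i) profile_row(10, 11, 4, 22, paste0("a", i)))),
    do.call(rbind, lapply(1:8, function(i) profile_row(15, 0, 0, 25, paste0("b", i)))))
  prof$population_id <- rep(c("p1", "p2"), c(2, 8))
  meta <- data.frame(population_id = c("p1", "p2"),
                     region = "Central Great Plains")
  s <- summarize_populations(prof, classify_profiles(prof), meta)
  r <- summarize_regions(s)
  expect_equal(r$p_A, 0.2)
  expect_equal(r$p_B, 0.8)
  expect_true(r$present_A && r$present_B && !r$present_C)
  # a single-population region equals that population's summary
  r1 <- summarize_regions(s[1, ])
  expect_equal(r1$p_A, s$p_A[1])
})
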
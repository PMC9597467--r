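two_arm <- function(x, y, genotype = "G1") {
  tibble::tibble(
    genotype = genotype,
    block = rep(1L, length(x) + length(y)),
    treatment = rep(c("non-F", "+F"), c(length(x), length(y))),
    plant_id = sprintf("p%d", seq_len(length(x) + length(y))),
    value = c(x, y)
  )
}

test_that("treatment contrast separates and respects the null", {
  sep <- treatment_contrast(two_arm(c(10, 10, 10), c(20, 20, 20)), "value")
  expect_true(sep$p_value < 1e-6)
  expect_true(sep$significant)

  null <- treatment_contrast(two_arm(c(5, 7, 9), c(5, 7, 9)), "value")
  expect_equal(null$t_statistic, 0)
  expect_equal(null$p_value, 1)

  expect_error(treatment_contrast(two_arm(1, c(2, 3)), "value"),
               ">= 2 plants per arm")
})

test_that("contrast power at the trial's effect size is near 1", {
  # effect ~54 g, plant SD 20, n = 12 per arm
  hits <- withr::with_seed(101, {
    sum(vapply(1:500, function(i) {
      d <- two_arm(rnorm(12, 100, 20), rnorm(12, 154, 20))
      treatment_contrast(d, "value")$p_value < 0.05
    }, TRUE))
  })
  expect_gte(hits / 500, 0.95)
})

test_that("tukey letters separate and merge as expected", {
  pt <- function(genos, values) {
    tibble::tibble(
      genotype = rep(genos, each = length(values)),
      block = 1L, treatment = "+F",
      plant_id = rep(sprintf("p%d", seq_along(values)), length(genos)),
      value = unlist(lapply(seq_along(genos), function(i) {
        values + (i - 1) * attr(values, "shift")
      }))
    )
  }
  vals <- c(1, 2, 3); attr(vals, "shift") <- 50
  lt <- tukey_letters(pt(c("A", "B"), vals), "value", "+F")
  expect_equal(sort(lt$letters), c("a", "b"))

  attr(vals, "shift") <- 0
  same <- tukey_letters(pt(c("A", "B", "C"), vals), "value", "+F")
  expect_true(all(same$letters == "a"))

  expect_error(tukey_letters(pt("A", vals), "value", "+F"), ">= 2 genotypes")
})

test_that("tukey p-values and letters match a studentized-range oracle", {
  withr::with_seed(33, {
    for (i in 1:10) {
      k <- sample(3:5, 1); n <- sample(3:6, 1)
      centers <- sample(c(0, 0, 5, 10), k, replace = TRUE)
      d <- tibble::tibble(
        genotype = rep(LETTERS[1:k], each = n),
        block = 1L, treatment = "non-F",
        plant_id = rep(sprintf("p%d", 1:n), k),
        value = rnorm(k * n, rep(centers, each = n), 2)
      )
      lt <- tukey_letters(d, "value", "non-F")
      pm <- attr(lt, "p_matrix")

      # oracle: balanced studentized range from first principles
      means <- tapply(d$value, d$genotype, mean)
      mse <- sum((d$value - rep(means, each = n))^2) / (k * (n - 1))
      oracle <- matrix(1, k, k, dimnames = list(names(means), names(means)))
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        q <- abs(means[a] - means[b]) / sqrt(mse / n)
        oracle[a, b] <- oracle[b, a] <-
          stats::ptukey(q, k, k * (n - 1), lower.tail = FALSE)
      }
      expect_equal(pm, oracle, tolerance = 1e-8)
      expect_equal(lt$letters,
                   unname(compact_letters(oracle, means)[lt$genotype]))
    }
  })
})

test_that("compact letter displays are consistent with their p-matrix", {
  withr::with_seed(77, {
    for (i in 1:50) {
      k <- sample(3:8, 1)
      p <- matrix(1, k, k, dimnames = list(LETTERS[1:k], LETTERS[1:k]))
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        p[a, b] <- p[b, a] <- runif(1)
      }
      means <- setNames(rnorm(k), LETTERS[1:k])
      lets <- compact_letters(p, means, alpha = 0.3)
      share <- function(a, b) {
        length(intersect(strsplit(lets[[a]], "")[[1]],
                         strsplit(lets[[b]], "")[[1]])) > 0
      }
      for (a in 1:(k - 1)) for (b in (a + 1):k) {
        ga <- LETTERS[a]; gb <- LETTERS[b]
        if (p[a, b] < 0.3) expect_false(share(ga, gb))
        else expect_true(share(ga, gb))
      }
    }
  })
})

test_that("pearson_r matches brute-force covariance and a permutation test", {
  withr::with_seed(55, {
    for (i in 1:10) {
      x <- rnorm(8); y <- rnorm(8)
      got <- pearson_r(x, y)
      r_brute <- sum((x - mean(x)) * (y - mean(y))) /
        sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
      expect_equal(got$r, r_brute, tolerance = 1e-12)
    }
  })
  x <- c(1, 3, 4, 6, 8, 9)
  expect_equal(pearson_r(x, 2 * x + 3)$r, 1)
  expect_error(pearson_r(x, rep(2, 6)), "zero variance")
  expect_error(pearson_r(x, x[-1]), "equal length")

  # permutation oracle on n = 6 pairs
  withr::with_seed(60, {
    x <- rnorm(6); y <- x * 0.5 + rnorm(6)
    got <- pearson_r(x, y)
    r_obs <- abs(got$r)
    perm <- mean(vapply(1:10000, function(i) {
      abs(cor(x, sample(y))) >= r_obs - 1e-12
    }, TRUE))
    se <- sqrt(perm * (1 - perm) / 10000)
    expect_lt(abs(perm - got$p_value), 4 * se + 0.02)
  })
})

test_that("split-plot ANOVA decomposes sums of squares additively", {
  records <- simulate_trial(sim_config(seed = 21))
  traits <- derive_traits(records)
  tab <- split_plot_anova(traits, "dry_tuber_g")
  sub <- traits |>
    dplyr::group_by(block, treatment, genotype) |>
    dplyr::summarize(value = mean(dry_tuber_g), .groups = "drop")
  total_ss <- sum((sub$value - mean(sub$value))^2)
  expect_equal(sum(tab$sum_sq), total_ss, tolerance = 1e-8)
  expect_setequal(tab$term[!grepl("Residuals", tab$term)],
                  c("treatment", "genotype", "treatment:genotype"))
  expect_equal(sum(tab$df), nrow(sub) - 1)
})

test_that("a pure treatment effect shows up as a treatment signal only", {
  base <- calibrate_genotype_params()
  flat <- base
  flat[-1] <- lapply(base[-1], function(col) rep(mean(col), nrow(base)))
  flat$resp_shoot <- rep(0.3, nrow(flat))
  flat$resp_tuber <- rep(0.3, nrow(flat)) # treatment effect, no genotype effect
  hits <- withr::with_seed(7, {
    rowSums(vapply(1:20, function(i) {
      tab <- split_plot_anova(
        derive_traits(simulate_trial(sim_config(seed = 1, genotypes = flat),
                                     seed = NULL)),
        "dry_tuber_g")
      c(T_sig = tab$p_value[tab$term == "treatment"] < 0.05,
        G_sig = tab$p_value[tab$term == "genotype"] < 0.05)
    }, c(T_sig = TRUE, G_sig = TRUE)))
  })
  expect_gt(hits[["T_sig"]], 10) # majority of runs detect the treatment
  expect_lt(hits[["G_sig"]], 10) # genotype stays at the null rate

  incomplete <- derive_traits(simulate_trial(sim_config(seed = 2)))
  incomplete <- incomplete[!(incomplete$genotype == "TDr1499" &
                               incomplete$block == 1), ]
  expect_error(split_plot_anova(incomplete, "dry_tuber_g"), "missing cells")
})
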
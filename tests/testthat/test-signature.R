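test_that("0-100 rescaling follows the printed affine form", {
  m <- cbind(s1 = c(2, 4, 6))
  expect_equal(unname(rescale_0_100(m)[, 1]), c(0, 50, 100))
  withr::with_seed(1, {
    M <- matrix(rnorm(60), 6, 10,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
    R <- rescale_0_100(M)
    expect_equal(unname(apply(R, 2, min)), rep(0, 10))
    expect_equal(unname(apply(R, 2, max)), rep(100, 10))
    # idempotent up to the affine map
    expect_equal(rescale_0_100(R), R, tolerance = 1e-12)
  })
  bad <- cbind(s1 = c(1, 2, 3), flatty = c(5, 5, 5))
  rownames(bad) <- paste0("g", 1:3)
  expect_error(rescale_0_100(bad), "flatty")
})

test_that("the metagene score is the signed per-arm mean formula", {
  # all-positive model on uniform expression collapses to that value
  m_all <- signature_model(paste0("g", 1:4), rep(1L, 4))
  X <- matrix(7, 4, 3, dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  X[1, ] <- 7 + 1e-9  # avoid the degenerate constant-sample case
  sc <- compute_score(X, m_all, rescale = FALSE)
  expect_equal(sc$score, rep((3 * 7 + 7 + 1e-9) / 4, 3), tolerance = 1e-12)
  # balanced arms with identical expression cancel to zero
  m_bal <- signature_model(paste0("g", 1:4), c(1L, 1L, -1L, -1L))
  Y <- rbind(g1 = c(1, 2), g2 = c(3, 4), g3 = c(1, 2), g4 = c(3, 4))
  colnames(Y) <- c("s1", "s2")
  expect_equal(compute_score(Y, m_bal, rescale = FALSE)$score, c(0, 0))
})

test_that("the score equals a brute-force signed sum on random models", {
  withr::with_seed(2, {
    for (rep in 1:20) {
      genes <- sprintf("g%02d", 1:20)
      co <- sample(c(-1L, 1L), 20, replace = TRUE)
      model <- signature_model(genes, co)
      X <- matrix(rnorm(200), 20, 10,
                  dimnames = list(genes, sprintf("s%02d", 1:10)))
      sc <- compute_score(X, model, rescale = FALSE)
      brute <- vapply(seq_len(10), function(j) {
        (sum(X[co == 1, j]) - sum(X[co == -1, j])) / 20
      }, numeric(1))
      expect_equal(sc$score, brute, tolerance = 1e-12)
      # invariant to permuting the model's gene order
      perm <- sample(20)
      sc2 <- compute_score(X, signature_model(genes[perm], co[perm]),
                           rescale = FALSE)
      expect_equal(sc2$score, sc$score, tolerance = 1e-12)
    }
  })
})

test_that("missing signature genes follow the 10% renormalization policy", {
  genes <- sprintf("g%02d", 1:20)
  model <- signature_model(genes, rep(c(1L, -1L), 10))
  withr::with_seed(3, {
    X <- matrix(rnorm(200), 20, 10,
                dimnames = list(genes, sprintf("s%02d", 1:10)))
    # one gene missing (5%): renormalize with a warning
    expect_warning(sc <- compute_score(X[-1, ], model, rescale = FALSE),
                   "renormalizing")
    manual <- (colSums(X[genes[-1][rep(c(1L, -1L), 10)[-1] == 1], ]) -
                 colSums(X[genes[-1][rep(c(1L, -1L), 10)[-1] == -1], ])) / 19
    expect_equal(sc$score, unname(manual), tolerance = 1e-12)
    # three genes missing (15%): hard error
    expect_error(suppressWarnings(compute_score(X[-(1:3), ], model)),
                 "missing")
  })
})

test_that("signature model construction and JSON round-trip are faithful", {
  expect_error(signature_model("g1", 2L), "\\+1 or -1")
  expect_error(signature_model(character(0), integer(0)), "at least one")
  m <- signature_model(c("g1", "g2", "g3"), c(1L, -1L, 1L), cutoff = 12.5,
                       provenance = list(split = "tertile"))
  f <- tempfile(fileext = ".json")
  write_signature(m, f)
  m2 <- read_signature(f)
  expect_equal(m2$genes, m$genes)
  expect_equal(m2$coefficients, m$coefficients)
  expect_equal(m2$cutoff, 12.5)
  unlink(f)
})

# survival data whose hazard rises with a latent risk; expression of
# "riskgene" tracks the risk, "protective" tracks its negative
filter_fixture <- function(n = 150, seed = 11, flip_probe = FALSE) {
  withr::with_seed(seed, {
    risk <- rnorm(n)
    cl <- tibble::tibble(
      sample = sprintf("s%03d", 1:n),
      time_months = rexp(n, 0.01 * 2.5^risk),
      event = 1L)
    probes <- rbind(
      riskgene_p1 = risk + rnorm(n, sd = 0.3),
      riskgene_p2 = (if (flip_probe) -risk else risk) + rnorm(n, sd = 0.3),
      protective_p1 = -risk + rnorm(n, sd = 0.3),
      noise_p1 = rnorm(n))
    colnames(probes) <- cl$sample
    map <- tibble::tibble(
      probe = rownames(probes),
      gene = sub("_p[12]$", "", rownames(probes)))
    list(clinical = cl, expr = probes, map = map)
  })
}

test_that("the univariate filter finds planted risk genes with the right sign", {
  fx <- filter_fixture()
  rec <- filter_prognostic(fx$clinical, fx$expr,
                           c("riskgene", "protective", "noise"),
                           probe_map = fx$map)
  expect_true(rec$passed[rec$gene == "riskgene"])
  expect_equal(rec$direction[rec$gene == "riskgene"], 1L)
  expect_true(rec$passed[rec$gene == "protective"])
  expect_equal(rec$direction[rec$gene == "protective"], -1L)
  expect_false(rec$passed[rec$gene == "noise"])
  expect_equal(rec$n_probes[rec$gene == "riskgene"], 2)
})

test_that("probes with opposite planted signs fail the consistency rule", {
  fx <- filter_fixture(flip_probe = TRUE)
  rec <- filter_prognostic(fx$clinical, fx$expr, "riskgene",
                           probe_map = fx$map)
  expect_false(rec$probes_consistent[rec$gene == "riskgene"])
  expect_false(rec$passed[rec$gene == "riskgene"])
})

test_that("quartile splits work and absent genes are skipped with a message", {
  fx <- filter_fixture()
  expect_message(
    rec <- filter_prognostic(fx$clinical, fx$expr,
                             c("riskgene", "ghost"),
                             probe_map = fx$map, split = "quartile"),
    "absent")
  expect_equal(nrow(rec), 1)
  expect_true(rec$passed[rec$gene == "riskgene"])
})

test_that("the filter's null pass rate matches its nominal level", {
  # expression independent of survival: a gene passes only by chance;
  # the log-rank condition alone holds ~1% of the time and the
  # monotonicity requirement can only lower that
  withr::with_seed(21, {
    n <- 120
    cl <- tibble::tibble(sample = sprintf("s%03d", 1:n),
                         time_months = rexp(n, 0.02), event = 1L)
    hits <- purrr::map_lgl(1:400, function(i) {
      e <- matrix(rnorm(n), 1, n,
                  dimnames = list("gX", cl$sample))
      filter_prognostic(cl, e, "gX")$passed
    })
    expect_lte(mean(hits), 0.03)
  })
})

test_that("CV classification labels every sample once, matching the scan oracle", {
  withr::with_seed(31, {
    n <- 100
    deceased <- rbinom(n, 1, 0.4)
    score <- deceased * 1.2 + rnorm(n)
    sc <- tibble::tibble(sample = sprintf("s%03d", 1:n),
                         score = score, deceased = deceased)
    cv <- cv_train_classify(sc, k = 5, seed = 7)
    expect_setequal(cv$results$sample, sc$sample)
    expect_equal(nrow(cv$results), n)
    expect_equal(anyDuplicated(cv$results$sample), 0)
    expect_equal(cv$cutoff, median(cv$fold_cutoffs))
    # every fold's cutoff equals the exhaustive scan on its training part
    folds <- with_seed_(7, caret::createFolds(factor(deceased), k = 5))
    for (i in seq_along(folds)) {
      tr <- setdiff(seq_len(n), folds[[i]])
      expect_equal(unique(cv$results$cutoff[cv$results$fold == i]),
                   oracle_best_cutoff(score[tr], deceased[tr]))
    }
    # reproducible under the same seed
    cv2 <- cv_train_classify(sc, k = 5, seed = 7)
    expect_identical(cv$results, cv2$results)
  })
})

test_that("a perfectly separating score classifies every fold perfectly", {
  withr::with_seed(32, {
    n <- 60
    deceased <- rep(c(0, 1), each = n / 2)
    score <- deceased * 10 + runif(n)
    sc <- tibble::tibble(sample = sprintf("s%03d", 1:n),
                         score = score, deceased = deceased)
    cv <- cv_train_classify(sc, k = 5, seed = 3)
    got <- cv$results |> dplyr::inner_join(sc, by = c("sample", "score"))
    expect_true(all((got$class == "High") == (got$deceased == 1)))
    cut <- roc_cutoff(score, deceased)
    expect_equal(cut$sensitivity + cut$specificity, 2)
  })
})

test_that("a null score classifies held-out samples at chance", {
  # the cutoff maximizes sensitivity + specificity, so under a null
  # score the held-out balanced accuracy (mean of sensitivity and
  # specificity) hovers at the chance level of 1/2, and raw accuracy
  # cannot systematically beat it
  withr::with_seed(33, {
    bacc <- purrr::map_dbl(1:100, function(i) {
      n <- 60
      deceased <- rbinom(n, 1, 0.35)
      if (sum(deceased) < 5 || sum(deceased) > n - 5) return(NA)
      sc <- tibble::tibble(sample = sprintf("s%03d", 1:n),
                           score = rnorm(n), deceased = deceased)
      cv <- suppressMessages(cv_train_classify(sc, k = 5, seed = i))
      got <- dplyr::inner_join(cv$results,
                               sc |> dplyr::select(sample, deceased),
                               by = "sample")
      sens <- mean(got$class[got$deceased == 1] == "High")
      spec <- mean(got$class[got$deceased == 0] == "Low")
      (sens + spec) / 2
    })
    expect_lt(abs(mean(bacc, na.rm = TRUE) - 0.5), 0.05)
  })
})

test_that("deceased labels honor the follow-up horizon", {
  cl <- tibble::tibble(time_months = c(50, 130, 80, 200),
                       event = c(1L, 1L, 0L, 0L))
  expect_equal(deceased_label(cl), c(1L, 1L, 0L, 0L))
  expect_equal(deceased_label(cl, horizon = 120), c(1L, 0L, 0L, 0L))
})

test_that("derive_signature recovers a planted program end to end", {
  cfg <- sim_config(n_cohorts = 2, cohort_sizes = c(120, 80),
                    dialects = c("logratio", "logratio"), n_genes = 120,
                    n_cn_driven = 8, n_prognostic = 12,
                    hazard_ratio = 2.5, seed = 41)
  st <- simulate_study(cfg)
  tr <- st$cohorts[[1]]
  sig <- derive_signature(tr$clinical, tr$expr,
                          st$truth$annotation$gene,
                          probe_map = tr$probe_map, max_steps = 40,
                          seed = 41)
  prog <- st$truth$prognostic
  found <- dplyr::inner_join(tidy(sig$model), prog, by = "gene")
  expect_gte(nrow(found), 9)                       # most of the program
  expect_gte(mean(found$coefficient == found$direction), 0.9)
  expect_true(is.finite(sig$model$cutoff))
  # flipping all planted directions flips the score-risk correlation
  flipped <- signature_model(sig$model$genes,
                             -sig$model$coefficients)
  s1 <- compute_score(tr$expr, sig$model, tr$probe_map)
  s2 <- compute_score(tr$expr, flipped, tr$probe_map)
  r <- tr$risk
  c1 <- cor(s1$score[match(r$sample, s1$sample)], r$risk)
  c2 <- cor(s2$score[match(r$sample, s2$sample)], r$risk)
  expect_gt(c1, 0.5)
  expect_equal(c2, -c1, tolerance = 1e-12)
})
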
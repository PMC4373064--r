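test_that("hypergeometric p matches exact enumeration", {
  study <- paste0("s", 1:10)
  background <- paste0("s", 1:100)
  term_map <- data.frame(
    element_id = c(study[1:5], paste0("s", 11:15)),
    term_id = "T1", stringsAsFactors = FALSE)
  res <- test_enrichment(study, background, term_map)
  expect_equal(res$p_value, enum_phyper_upper(5L, 10L, 100L, 10L),
               tolerance = 1e-14)
  # K = N and k = n is the certain event
  all_map <- data.frame(element_id = background, term_id = "T1",
                        stringsAsFactors = FALSE)
  expect_equal(test_enrichment(study, background, all_map)$p_value, 1.0)
  expect_error(test_enrichment(character(0), background, term_map), "empty")
  expect_error(test_enrichment(c(study, "zz"), background, term_map),
               "absent from background")
})

test_that("p is non-increasing in the study hit count k", {
  N <- 200L; K <- 40L; n <- 30L
  p <- vapply(1:30, function(k) {
    stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  }, numeric(1))
  expect_true(all(diff(p) <= 0))
  # and the module reproduces those tails through its public interface
  background <- paste0("e", seq_len(N))
  annotated <- paste0("e", seq_len(K))
  for (k in c(5L, 15L, 25L)) {
    study <- c(annotated[seq_len(k)], paste0("e", seq.int(K + 1L, K + n - k)))
    res <- test_enrichment(study, background,
                           data.frame(element_id = annotated, term_id = "T",
                                      stringsAsFactors = FALSE))
    expect_equal(res$p_value, p[k], tolerance = 1e-14)
  }
})

test_that("Bonferroni correction spans the tested terms and sorts output", {
  set.seed(77)
  background <- paste0("e", 1:300)
  study <- paste0("e", 1:30)
  term_map <- rbind(
    data.frame(element_id = study[1:12], term_id = "T_hot",
               stringsAsFactors = FALSE),
    data.frame(element_id = sample(background, 60L), term_id = "T_base",
               stringsAsFactors = FALSE),
    data.frame(element_id = sample(background, 40L), term_id = "T_other",
               stringsAsFactors = FALSE))
  res <- test_enrichment(study, background, term_map)
  m <- nrow(res)
  expect_equal(res$corrected_p, pmin(1, res$p_value * m))
  expect_false(is.unsorted(res$corrected_p))
  expect_true(res$enriched[res$term_id == "T_hot"])
  fdr <- test_enrichment(study, background, term_map, correction = "fdr")
  expect_equal(sort(fdr$corrected_p),
               sort(stats::p.adjust(res$p_value, method = "BH")),
               tolerance = 1e-12)
})
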
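test_that("phase windows partition the cycle", {
  w <- phase_windows(0.33)
  expect_equal(w$lo, c(0, 0.33, 0.665))
  expect_equal(w$hi[3], 1)
  expect_error(phase_windows(0.8, 0.3))
})

test_that("window labeling follows the significant-fraction rule", {
  # hand-built profile: strong significant inhibition across post-I only
  n <- 100
  centers <- (1:n - 0.5) / n
  prof <- data.frame(
    phase_center = centers, valid = TRUE,
    dGi_dyn = ifelse(centers >= 0.33 & centers < 0.66, 5, 0),
    dGe_dyn = 0,
    sig_i = centers >= 0.33 & centers < 0.66,
    sig_e = FALSE)
  lab <- classify_inputs(prof, phase_windows(0.33))
  pi_i <- lab$present[lab$window == "post_I" & lab$sign == "inhibitory"]
  expect_true(pi_i)
  expect_equal(sum(lab$present), 1)
  expect_equal(lab$peak[lab$present], 5)

  # no significant bins anywhere: nothing labeled
  prof2 <- prof
  prof2$sig_i <- FALSE
  expect_equal(sum(classify_inputs(prof2, phase_windows(0.33))$present), 0)
})

test_that("the full pipeline labels the ramp-I input pattern", {
  sim <- make_phenotype_fixture("ramp-I", seed = 1L, noise_sd = 0.5)
  w <- phase_windows(sim$truth$protocol$inspiratory_fraction)
  fit <- syncond(sim$recording, phenotype = "ramp-I", windows = w)
  lab <- fit$labels
  get <- function(win, sgn) lab$present[lab$window == win &
                                          lab$sign == sgn]
  expect_true(get("post_I", "inhibitory"))
  expect_true(get("E2", "inhibitory"))
  expect_true(get("I", "excitatory"))
  expect_false(get("I", "inhibitory"))
})

test_that("motif inference attributes inputs to the right populations", {
  sim <- make_phenotype_fixture("ramp-I", seed = 1L, noise_sd = 0.5)
  w <- phase_windows(sim$truth$protocol$inspiratory_fraction)
  fit <- syncond(sim$recording, phenotype = "ramp-I", windows = w)
  e <- fit$motifs$edges
  has <- function(src, sgn) any(e$source == src & e$sign == sgn)
  expect_true(has("post-I", "inhibitory"))
  expect_true(has("aug-E", "inhibitory"))
  expect_true(has("pre-I/I", "excitatory"))

  sim2 <- make_phenotype_fixture("pre-I/I", seed = 1L, noise_sd = 0.5)
  w2 <- phase_windows(sim2$truth$protocol$inspiratory_fraction)
  fit2 <- syncond(sim2$recording, phenotype = "pre-I/I", windows = w2)
  e2 <- fit2$motifs$edges
  has2 <- function(src, sgn) any(e2$source == src & e2$sign == sgn)
  expect_true(has2("post-I", "inhibitory"))
  expect_true(has2("aug-E", "excitatory"))
  expect_true(has2("ramp-I", "excitatory"))
})

test_that("an unlabeled profile yields an empty edge list", {
  n <- 100
  prof <- data.frame(
    phase_center = (1:n - 0.5) / n, valid = TRUE,
    dGi_dyn = 0, dGe_dyn = 0, sig_i = FALSE, sig_e = FALSE)
  m <- infer_motif(prof, target = "ramp-I")
  expect_equal(nrow(m$edges), 0)
})

test_that("raising alpha can only add edges, never remove them", {
  sim <- make_phenotype_fixture("late-I", seed = 2L, noise_sd = 0.5)
  w <- phase_windows(sim$truth$protocol$inspiratory_fraction)
  fit <- syncond(sim$recording, windows = w)
  edges_at <- function(alpha) {
    cfg <- sc_config(alpha = alpha)
    prof <- conductance_profile(fit$conductance, fit$regression$V0,
                                reversal_pair(fit$reversals$e_i,
                                              fit$reversals$e_e),
                                cfg)
    m <- infer_motif(prof, target = "late-I", windows = w)
    paste(m$edges$source, m$edges$sign)
  }
  e1 <- edges_at(0.001)
  e2 <- edges_at(0.05)
  e3 <- edges_at(0.2)
  expect_true(all(e1 %in% e2))
  expect_true(all(e2 %in% e3))
})

test_that("edge lists export as delimited text", {
  sim <- make_phenotype_fixture("aug-E", seed = 1L, noise_sd = 0.5)
  w <- phase_windows(sim$truth$protocol$inspiratory_fraction)
  fit <- syncond(sim$recording, phenotype = "aug-E", windows = w)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_motif_edges(fit$motifs, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(fit$motifs$edges))
  expect_true(all(c("source", "sign", "target", "windows", "score") %in%
                    names(back)))
})
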
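#' Canonical respiratory firing phenotypes
#'
#' Names of the six canonical firing phenotypes of respiratory
#' interneurons, defined by when in the cycle they fire: pre-inspiratory/
#' inspiratory, ramping inspiratory, early-inspiratory, late-inspiratory,
#' post-inspiratory and augmenting expiratory.
#'
#' @return Character vector of phenotype names.
#' @export
phenotype_names <- function() {
  c("pre-I/I", "ramp-I", "early-I", "late-I", "post-I", "aug-E")
}

#' Population activity template of a firing phenotype
#'
#' Returns the canonical normalized (peak 1) firing-rate envelope of a
#' phenotype as a function of cycle phase, using the three-phase cycle
#' partition with inspiration on `[0, 0.33)`, post-inspiration on
#' `[0.33, 0.66)` and late expiration (E2) on `[0.66, 1)`:
#' \describe{
#'   \item{pre-I/I}{rises during late expiration (from phase 0.85) and
#'     stays active throughout inspiration}
#'   \item{ramp-I}{augmenting (ramping) through inspiration}
#'   \item{early-I}{decrementing through inspiration}
#'   \item{late-I}{a late-inspiratory bell (phases 0.12-0.33)}
#'   \item{post-I}{decrementing through post-inspiration}
#'   \item{aug-E}{augmenting through late expiration}
#' }
#' These same templates parameterize the simulator's phenotype fixtures
#' and the connectome matching step, so fixture construction and motif
#' inference share one source of truth.
#'
#' @param name a phenotype name, see [phenotype_names()].
#' @return A vectorized function of phase in `[0, 1)`.
#' @export
phenotype_activity <- function(name) {
  name <- match.arg(name, phenotype_names())
  half_up <- function(u) (1 - cos(pi * u)) / 2
  half_down <- function(u) (1 + cos(pi * u)) / 2
  switch(name,
    "pre-I/I" = function(phi) {
      phi <- phi %% 1
      out <- numeric(length(phi))
      rise <- phi >= 0.85
      out[rise] <- half_up((phi[rise] - 0.85) / 0.15)
      out[phi < 0.33] <- 1
      out
    },
    "ramp-I" = function(phi) {
      phi <- phi %% 1
      ifelse(phi < 0.33, half_up(phi / 0.33), 0)
    },
    "early-I" = function(phi) {
      phi <- phi %% 1
      ifelse(phi < 0.33, half_down(phi / 0.33), 0)
    },
    "late-I" = function(phi) {
      phi <- phi %% 1
      inb <- phi >= 0.12 & phi < 0.33
      out <- numeric(length(phi))
      out[inb] <- (1 - cos(2 * pi * (phi[inb] - 0.12) / 0.21)) / 2
      out
    },
    "post-I" = function(phi) {
      phi <- phi %% 1
      inb <- phi >= 0.33 & phi < 0.66
      out <- numeric(length(phi))
      out[inb] <- half_down((phi[inb] - 0.33) / 0.33)
      out
    },
    "aug-E" = function(phi) {
      phi <- phi %% 1
      inb <- phi >= 0.66
      out <- numeric(length(phi))
      out[inb] <- half_up((phi[inb] - 0.66) / 0.34)
      out
    })
}

#' Phenotype activity templates on the bin grid
#'
#' @param n_bins number of phase bins.
#' @return A matrix of `n_bins` rows and one column per phenotype, each
#'   column the activity sampled at bin centers (peak-normalized).
#' @export
phenotype_templates <- function(n_bins = 100L) {
  centers <- (seq_len(n_bins) - 0.5) / n_bins
  vapply(phenotype_names(),
         function(nm) phenotype_activity(nm)(centers),
         numeric(n_bins))
}

# Ground-truth synaptic input recipe per recorded phenotype: which source
# populations drive it, with what sign and peak conductance (nS). These
# mixes realize the characteristic conductance patterns of each phenotype:
# e.g. pre-I/I cells receive decrementing expiratory inhibition (post-I
# source), augmenting late-expiratory excitation (aug-E) and ramping
# inspiratory excitation (ramp-I).
phenotype_recipe <- function(name) {
  name <- match.arg(name, phenotype_names())
  switch(name,
    "pre-I/I" = list(gi = c("post-I" = 6),
                     ge = c("aug-E" = 3, "ramp-I" = 4)),
    "ramp-I" = list(gi = c("post-I" = 6, "aug-E" = 5),
                    ge = c("pre-I/I" = 4)),
    "early-I" = list(gi = c("post-I" = 6),
                     ge = c("pre-I/I" = 4)),
    "late-I" = list(gi = c("post-I" = 5, "aug-E" = 4, "early-I" = 3),
                    ge = c("ramp-I" = 4)),
    "post-I" = list(gi = c("early-I" = 6, "aug-E" = 4),
                    ge = c("post-I" = 2, "ramp-I" = 2.5)),
    "aug-E" = list(gi = c("early-I" = 5, "post-I" = 5),
                   ge = c("aug-E" = 3)))
}

#' Ground-truth functional inputs of a phenotype fixture
#'
#' @param name a phenotype name.
#' @return A data frame `source`, `sign` listing the source populations
#'   mixed into the fixture's conductance waveforms.
#' @export
phenotype_truth_edges <- function(name) {
  rec <- phenotype_recipe(name)
  data.frame(
    source = c(names(rec$gi), names(rec$ge)),
    sign = c(rep("inhibitory", length(rec$gi)),
             rep("excitatory", length(rec$ge))),
    stringsAsFactors = FALSE)
}

#' Simulated recording of a canonical firing phenotype
#'
#' Builds a quality-control-passing fixture (4 held levels of 6 cycles
#' each by default) whose inhibitory and excitatory conductance waveforms
#' are weighted sums of the canonical source-population activity
#' templates for that phenotype (see [phenotype_activity()] and
#' [phenotype_truth_edges()]), plus small static floors. Deterministic
#' given the seed.
#'
#' @param phenotype a phenotype name, see [phenotype_names()].
#' @param seed RNG seed.
#' @param mode clamp mode.
#' @param noise_sd mV-equivalent noise sd.
#' @param levels held levels (defaults depend on mode).
#' @param cycles_per_level cycles per step.
#' @return As [simulate_neuron()]; `truth` additionally carries
#'   `phenotype` and `edges`.
#' @export
make_phenotype_fixture <- function(phenotype, seed = 1L,
                                   mode = c("current_clamp",
                                            "voltage_clamp"),
                                   noise_sd = 0.5, levels = NULL,
                                   cycles_per_level = 6L) {
  phenotype <- match.arg(phenotype, phenotype_names())
  mode <- match.arg(mode)
  if (is.null(levels)) {
    levels <- if (mode == "current_clamp") {
      c(-200, -300, -400, -500)
    } else {
      c(-95, -85, -75, -65)
    }
  }
  rec <- phenotype_recipe(phenotype)
  mix_fun <- function(weights, floor_ns) {
    funs <- lapply(names(weights), phenotype_activity)
    w <- as.numeric(weights)
    function(phi) {
      out <- rep(floor_ns, length(phi))
      for (k in seq_along(funs)) out <- out + w[k] * funs[[k]](phi)
      out
    }
  }
  gi <- mix_fun(rec$gi, 0.5)
  ge <- mix_fun(rec$ge, 0.3)
  proto <- clamp_protocol(mode, levels = levels,
                          cycles_per_level = cycles_per_level)
  sim <- simulate_neuron(neuron_params(), gi, ge, proto,
                         noise_sd = noise_sd, seed = seed)
  sim$truth$phenotype <- phenotype
  sim$truth$edges <- phenotype_truth_edges(phenotype)
  sim
}
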
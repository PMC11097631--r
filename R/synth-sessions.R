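# Two-session ensemble generator with planted drift.

#' Generate two sessions of ensemble-structured responses
#'
#' K latent ensembles; each assigned sound belongs to exactly one ensemble
#' (unassigned sounds drive none). Every neuron carries a loading vector
#' over ensembles (i.i.d. uniform); the response of neuron n to sound s on
#' one repetition is its loading on the sound's ensemble plus Gaussian
#' noise, rectified at zero. Session 2 reuses the loadings except for a
#' `drift_fraction` of neurons, whose loading vectors are redrawn
#' independently (planted representational drift).
#'
#' @param config an [ensemble_config()]
#' @return list with `session1`, `session2` (`cell_vector_set` arrays,
#'   sound x rep x neuron) and `truth` (sound-to-ensemble map, loadings per
#'   session, drifted neuron indices)
#' @export
generate_two_sessions <- function(config) {
  stopifnot(inherits(config, "ensemble_config"))
  S <- config$n_sounds; K <- config$n_ensembles
  N <- config$n_neurons; R <- config$n_rep
  with_seed(config$rng_seed, {
    n_assigned <- S - config$n_unassigned
    # sounds distributed over ensembles as evenly as possible
    ens_of_sound <- c(rep(seq_len(K), length.out = n_assigned),
                      rep(0L, config$n_unassigned))
    loadings1 <- matrix(stats::runif(N * K), N, K)
    drifted <- sort(sample.int(N, round(config$drift_fraction * N)))
    loadings2 <- loadings1
    if (length(drifted))
      loadings2[drifted, ] <- stats::runif(length(drifted) * K)
    make_session <- function(load) {
      arr <- array(0, dim = c(S, R, N),
                   dimnames = list(sprintf("snd%02d", seq_len(S)), NULL,
                                   sprintf("n%03d", seq_len(N))))
      for (s in seq_len(S)) {
        mu <- if (ens_of_sound[s] > 0) load[, ens_of_sound[s]] else
          numeric(N)
        for (r in seq_len(R))
          arr[s, r, ] <- pmax(mu + stats::rnorm(N, 0, config$noise_sd), 0)
      }
      structure(arr, class = c("cell_vector_set", "array"))
    }
    s1 <- make_session(loadings1)
    s2 <- make_session(loadings2)
    list(session1 = s1, session2 = s2,
         truth = list(ens_of_sound = ens_of_sound, loadings1 = loadings1,
                      loadings2 = loadings2, drifted = drifted))
  })
}
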
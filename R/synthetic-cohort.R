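# Truth-known cohort simulator: paired (delta RQ, sham-referenced delta
# respiration) draws with a prescribed Pearson correlation.

#' Simulate a cohort linking blood mtDNA deltas to respiration deficits
#'
#' Draws `n` animals whose pre-to-post change in relative mtDNA copy number
#' (`delta_rq`) and sham-referenced respiration deficit
#' (`delta_resp = sham_mean - post_resp`) follow a bivariate normal
#' distribution with correlation `true_r`. A positive `true_r` means larger
#' mtDNA increases accompany larger bioenergetic deficits.
#'
#' @param seed Integer seed.
#' @param n Number of animals (>= 3).
#' @param true_r Population Pearson correlation in `[-1, 1]`.
#' @param sham_mean_flux Group sham mean of the respiration endpoint
#'   (pmol O2/s/mg for OXPHOS, dimensionless for RCR). Default 82.6, the
#'   healthy hippocampal OXPHOS(CI+CII) reference of the modelled assay.
#' @param effect_scales List with `delta_rq_mean`, `delta_rq_sd`,
#'   `delta_resp_mean`, `delta_resp_sd` giving the marginal moments of the
#'   two deltas.
#' @param group Group label stored on every record.
#' @param endpoint Respiration endpoint label (e.g. `"OXPHOS_CI+CII"` or
#'   `"RCR"`).
#'
#' @return Data frame of class `cohort_records` with columns `animal_id`,
#'   `group`, `endpoint`, `delta_rq`, `post_resp`, `sham_mean`, plus a
#'   `truth` attribute recording `true_r` and the effect scales.
#' @examples
#' co <- make_cohort(1, n = 20, true_r = 0.8)
#' cor(co$delta_rq, co$sham_mean - co$post_resp)
#' @export
make_cohort <- function(seed, n, true_r, sham_mean_flux = 82.6,
                        effect_scales = list(delta_rq_mean = 1.2,
                                             delta_rq_sd = 0.6,
                                             delta_resp_mean = 25,
                                             delta_resp_sd = 15),
                        group = "RNR-6h", endpoint = "OXPHOS_CI+CII") {
  if (!.is_number(true_r) || abs(true_r) > 1) {
    stop("'true_r' must lie in [-1, 1]", call. = FALSE)
  }
  stopifnot(.is_count(n, min = 3), .is_number(sham_mean_flux))
  es <- effect_scales
  needed <- c("delta_rq_mean", "delta_rq_sd", "delta_resp_mean", "delta_resp_sd")
  stopifnot(all(needed %in% names(es)), es$delta_rq_sd >= 0, es$delta_resp_sd >= 0)

  withr::with_seed(as.integer(seed), {
    z1 <- rnorm(n)
    z2 <- rnorm(n)
    zc <- true_r * z1 + sqrt(1 - true_r^2) * z2
    delta_rq <- es$delta_rq_mean + es$delta_rq_sd * z1
    delta_resp <- es$delta_resp_mean + es$delta_resp_sd * zc
    out <- data.frame(
      animal_id = sprintf("%s_a%02d", group, seq_len(n)),
      group = group, endpoint = endpoint,
      delta_rq = delta_rq,
      post_resp = sham_mean_flux - delta_resp,
      sham_mean = sham_mean_flux,
      stringsAsFactors = FALSE
    )
    attr(out, "truth") <- list(true_r = true_r, effect_scales = es,
                               delta_resp = delta_resp)
    class(out) <- c("cohort_records", "data.frame")
    out
  })
}
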
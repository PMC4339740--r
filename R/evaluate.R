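#' Estimate decoding-error probabilities over a channel grid
#'
#' For each per-symbol error probability `p_mut`, simulates a batch of
#' reads conditioned on the barcode being hit by at least one error event
#' (defective reads), decodes them, and estimates the conditional error
#' `Pr(err | def)` as the misassignment fraction. Error-free barcodes
#' decode perfectly under both decoders, so non-defective reads are counted
#' as correct without simulating them, and the unconditioned error is
#' `P_e = Pr(err | def) * Pr(def)` with `Pr(def) = 1 - (1 - p_mut)^N`.
#' Misassignment is judged on message indices, not sequences.
#'
#' @param set a `barcode_set` (non-empty).
#' @param p_mut_grid vector of per-symbol error probabilities (> 0).
#' @param batch_size defective reads per grid point.
#' @param I,Delta decoder HMM settings (see [hmm_params()]).
#' @param mode decoder mode, see [decode()].
#' @return data.frame of class `evaluation_result` with columns `p_mut`,
#'   `batch_size`, `n_errors`, `err_given_def`, `pr_def`, `p_e`.
#' @export
evaluate_code <- function(set, p_mut_grid, batch_size = 2000L,
                          I = 2L, Delta = 10L,
                          mode = c("symbolwise", "optimal")) {
  mode <- match.arg(mode)
  stopifnot(inherits(set, "barcode_set"))
  if (length(set$barcodes) == 0L) stop("empty barcode set")
  if (any(p_mut_grid <= 0)) {
    stop("conditioning impossible: p_mut must be positive to observe defects")
  }
  N <- set$config$N
  rows <- lapply(p_mut_grid, function(pm) {
    params <- channel_params(p_mut = pm)
    H <- hmm_from_pmut(pm, I = I, Delta = Delta)
    batch <- make_batch(set, params, batch_size, defective_only = TRUE)
    asg <- demux_reads(batch$reads, set, H, mode)
    err <- sum(is.na(asg$index) | asg$index != batch$truth$index)
    egd <- err / batch_size
    pdef <- pr_defective(pm, N)
    data.frame(p_mut = pm, batch_size = batch_size, n_errors = err,
               err_given_def = egd, pr_def = pdef, p_e = egd * pdef)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("evaluation_result", "data.frame")
  out
}
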
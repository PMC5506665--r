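#' Simulate a histone-PTM relative-abundance table
#'
#' Plants a replicate table for H3 K4/K9/K27/K36 modification states with a
#' single true effect: an `effect_fold` reduction of H3K9me2 in the treated
#' condition, compensated by a matching increase of unmodified H3K9 (the
#' pattern expected when both methyl groups of the dimethyl mark are
#' removed). Gaussian noise of sd `sd` is added to every abundance and each
#' (site, condition, replicate) block is renormalised to sum to 1, so the
#' output always satisfies the table invariant enforced by
#' [validate_ptm_table()].
#'
#' @param n_rep Replicates per condition (default 3, i.e. biological
#'   triplicates).
#' @param sd Per-abundance Gaussian noise (default 0.01).
#' @param effect_fold Planted H3K9me2 reduction (default 2.6).
#' @param seed Integer seed.
#' @return A validated PTM tibble (`site`, `state`, `condition`,
#'   `replicate`, `abundance`).
#' @export
sim_ptm_table <- function(n_rep = 3, sd = 0.01, effect_fold = 2.6, seed = 1) {
  set.seed(seed)
  base <- list(
    H3K4 = c(me0 = 0.55, me1 = 0.25, me2 = 0.10, me3 = 0.05, ac = 0.05),
    H3K9 = c(me0 = 0.15, me1 = 0.20, me2 = 0.30, me3 = 0.30, ac = 0.05),
    H3K27 = c(me0 = 0.10, me1 = 0.25, me2 = 0.35, me3 = 0.25, ac = 0.05),
    H3K36 = c(me0 = 0.40, me1 = 0.20, me2 = 0.25, me3 = 0.15)
  )
  treated_prof <- base
  lost <- base$H3K9[["me2"]] * (1 - 1 / effect_fold)
  treated_prof$H3K9[["me2"]] <- base$H3K9[["me2"]] / effect_fold
  treated_prof$H3K9[["me0"]] <- base$H3K9[["me0"]] + lost
  rows <- list()
  for (cond in c("untreated", "treated")) {
    prof <- if (cond == "untreated") base else treated_prof
    for (rep_i in seq_len(n_rep)) {
      for (site in names(prof)) {
        ab <- pmax(prof[[site]] + stats::rnorm(length(prof[[site]]), 0, sd), 0)
        ab <- ab / sum(ab)
        rows[[length(rows) + 1L]] <- tibble(
          site = site, state = names(prof[[site]]), condition = cond,
          replicate = rep_i, abundance = as.numeric(ab)
        )
      }
    }
  }
  validate_ptm_table(bind_rows(rows))
}
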
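# Conversion of ensemble association probabilities to association rate
# constants,
#   kon_i = kon_min * 10^((P_i - P_min) / (P_max - P_min) * N),
# and benchmark-level agreement statistics (log-ratio errors, Pearson
# correlation on log10 rates, omega and criteria scans).

#' Probability-to-rate conversion model
#'
#' `kon_min` is the lowest experimentally measured rate in the benchmark
#' (default 1.03e5 M^-1 s^-1) and `N` the number of orders of magnitude
#' the benchmark spans (default 4, i.e. rates up to ~1e9). `P_min` and
#' `P_max` are the extreme association probabilities over the analyzed
#' complex set.
#'
#' @param P_min,P_max probability range anchors, `0 <= P_min < P_max <= 1`.
#' @param kon_min rate at `P = P_min` (M^-1 s^-1).
#' @param N orders of magnitude spanned.
#' @return Object of class `rate_model`.
#' @export
rate_model <- function(P_min, P_max, kon_min = 1.03e5, N = 4) {
  stopifnot(kon_min > 0, N > 0, P_min >= 0, P_max <= 1)
  if (P_max <= P_min)
    stop("degenerate ensemble: P_max must exceed P_min")
  structure(list(P_min = P_min, P_max = P_max, kon_min = kon_min, N = N),
            class = "rate_model")
}

#' @rdname rate_model
#' @param P vector of association probabilities whose range sets
#'   `P_min`/`P_max`.
#' @export
rate_model_from_probs <- function(P, kon_min = 1.03e5, N = 4) {
  rate_model(min(P), max(P), kon_min, N)
}

#' Convert association probabilities to rate constants
#'
#' `log10(kon)` is affine in `P`: `P = P_min` maps to `kon_min`, `P =
#' P_max` to `kon_min * 10^N`. Probabilities outside `[P_min, P_max]`
#' (possible when a fixed model is applied to new complexes) are flagged
#' in the `"censored"` attribute as `"below_range"` / `"above_range"`,
#' i.e. the rate should be read as "< kon_min" / "> kon_min * 10^N".
#'
#' @param P association probabilities in `[0, 1]`.
#' @param model a [rate_model()].
#' @return numeric vector of rates (M^-1 s^-1) with attribute `censored`.
#' @export
probability_to_rate <- function(P, model) {
  stopifnot(inherits(model, "rate_model"), all(P >= 0), all(P <= 1))
  expo <- (P - model$P_min) / (model$P_max - model$P_min) * model$N
  kon <- model$kon_min * 10^expo
  cens <- rep("", length(P))
  cens[P < model$P_min] <- "below_range"
  cens[P > model$P_max] <- "above_range"
  attr(kon, "censored") <- cens
  kon
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation with the precondition checks used
#' throughout the benchmark analyses (length >= 3, nonzero variance).
#' Rate comparisons are made on `log10(kon)`.
#'
#' @param x,y numeric vectors of equal length.
#' @return the correlation coefficient.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  stats::cor(x, y)
}

#' Log-ratio prediction errors over a benchmark
#'
#' Computes `log10(kon_calc / kon_exp)` per complex. A prediction is an
#' error when the absolute log ratio exceeds 1 (more than one order of
#' magnitude off); positive errors are overestimates, negative
#' underestimates. Accuracy is the fraction within one order of
#' magnitude.
#'
#' @param kon_calc,kon_exp simulated and experimental rates (M^-1 s^-1).
#' @return list with `log_ratio` (per complex), `n_over`, `n_under`,
#'   `n_errors`, `n_correct`, `accuracy`.
#' @export
log_ratio_errors <- function(kon_calc, kon_exp) {
  stopifnot(length(kon_calc) == length(kon_exp),
            all(kon_calc > 0), all(kon_exp > 0))
  lr <- log10(kon_calc / kon_exp)
  over <- lr > 1
  under <- lr < -1
  list(log_ratio = lr,
       n_over = sum(over),
       n_under = sum(under),
       n_errors = sum(over | under),
       n_correct = sum(!(over | under)),
       accuracy = mean(!(over | under)))
}

#' Scan the force-field mixing weight
#'
#' Re-runs the full ensemble of every benchmark complex at each value of
#' the statistical-potential weight `omega` (Metropolis acceptance depends
#' on `omega`, so cached energy components cannot substitute for
#' re-simulation), converts probabilities to rates with `P_min`/`P_max`
#' recomputed per `omega`, and reports the Pearson correlation with the
#' experimental rates (on log10 scale) and the error count.
#'
#' @param complexes list of benchmark entries; each a list with elements
#'   `receptor`, `ligand`, `contacts`, `config`, `kon_exp`, and optionally
#'   `xi` (per-complex Debye length from the measurement's ionic
#'   strength).
#' @param ff a [hybrid_forcefield()] template whose `omega` is replaced
#'   per scan point.
#' @param omegas numeric vector of weights in `[0, 1]`.
#' @param kon_min,N rate-model constants.
#' @return data.frame with one row per omega: `omega`, `pcc`, `n_errors`,
#'   plus attribute `details` (per-omega data.frame of `P` and `kon` per
#'   complex).
#' @export
omega_scan <- function(complexes, ff, omegas, kon_min = 1.03e5, N = 4) {
  stopifnot(length(complexes) >= 1, all(omegas >= 0), all(omegas <= 1))
  details <- list()
  rows <- lapply(omegas, function(w) {
    ff_w <- ff
    ff_w$omega <- w
    P <- vapply(complexes, function(cx) {
      if (!is.null(cx$xi)) ff_w$physics$xi <- cx$xi
      run_ensemble(cx$receptor, cx$ligand, ff_w, cx$contacts, cx$config)$P
    }, numeric(1))
    kon_exp <- vapply(complexes, `[[`, numeric(1), "kon_exp")
    if (max(P) - min(P) <= 0) {
      # degenerate ensemble: no rate model is defined for this omega
      details[[as.character(w)]] <<- data.frame(omega = w, P = P,
                                                kon = NA_real_,
                                                kon_exp = kon_exp)
      return(data.frame(omega = w, pcc = NA_real_,
                        n_errors = NA_integer_))
    }
    model <- rate_model_from_probs(P, kon_min, N)
    kon <- probability_to_rate(P, model)
    details[[as.character(w)]] <<- data.frame(omega = w, P = P, kon = kon,
                                              kon_exp = kon_exp)
    err <- log_ratio_errors(kon, kon_exp)
    data.frame(omega = w,
               pcc = pearson_correlation(log10(kon), log10(kon_exp)),
               n_errors = err$n_errors)
  })
  out <- do.call(rbind, rows)
  attr(out, "details") <- details
  out
}

# Association outcome of each trajectory of a summary table under a set
# of post-hoc thresholds (conjunctive; NULL / NA thresholds inactive).
apply_criteria_post_hoc <- function(summary, min_contacts = NULL,
                                    min_pct = NULL, max_rmsd = NULL,
                                    max_ifd = NULL, max_energy = NULL) {
  ok <- rep(TRUE, nrow(summary))
  if (!is.null(min_contacts) && !is.na(min_contacts))
    ok <- ok & summary$final_native_contacts >= min_contacts
  if (!is.null(min_pct) && !is.na(min_pct))
    ok <- ok & summary$final_contact_pct >= min_pct
  if (!is.null(max_rmsd) && !is.na(max_rmsd))
    ok <- ok & summary$final_rmsd <= max_rmsd
  if (!is.null(max_ifd) && !is.na(max_ifd))
    ok <- ok & summary$final_interface_distance <= max_ifd
  if (!is.null(max_energy) && !is.na(max_energy))
    ok <- ok & summary$final_energy <= max_energy
  ok
}

#' Scan combinations of association criteria
#'
#' Post-hoc re-evaluation of association over ensembles that were run with
#' early termination disabled, so every trajectory carries its final
#' diagnostics. For every combination of thresholds on the grids
#' (restored-contact count, restored percentage, RMSD, interface distance,
#' energy; `NA` in a grid deactivates that criterion for the combination)
#' the per-complex association probabilities, rates and the Pearson
#' correlation with experiment are recomputed. The default grids follow
#' the benchmark protocol: contacts 0-10 by 1, percentage 0-10% by 1,
#' RMSD 0-30 A by 3, interface distance 0-10 A by 1, energy 0 to -30 kT
#' by 3.
#'
#' @param summaries list of per-complex ensemble summary data.frames (from
#'   [run_ensemble()] with `terminate_on_association = FALSE`).
#' @param kon_exp experimental rates, one per complex.
#' @param grids named list of threshold grids (`min_contacts`, `min_pct`,
#'   `max_rmsd`, `max_ifd`, `max_energy`).
#' @param kon_min,N rate-model constants.
#' @return list with `table` (one row per combination: thresholds, `pcc`,
#'   `n_errors`; combinations whose probabilities are degenerate get `NA`)
#'   and `best` (the row with the highest PCC).
#' @export
criteria_scan <- function(summaries, kon_exp,
                          grids = list(min_contacts = 0:10,
                                       min_pct = 0:10,
                                       max_rmsd = seq(0, 30, 3),
                                       max_ifd = 0:10,
                                       max_energy = seq(0, -30, -3)),
                          kon_min = 1.03e5, N = 4) {
  stopifnot(length(summaries) == length(kon_exp), length(summaries) >= 3)
  defaults <- list(min_contacts = NA, min_pct = NA, max_rmsd = NA,
                   max_ifd = NA, max_energy = NA)
  for (nm in names(defaults))
    if (is.null(grids[[nm]])) grids[[nm]] <- defaults[[nm]]
  combos <- expand.grid(grids[c("min_contacts", "min_pct", "max_rmsd",
                                "max_ifd", "max_energy")],
                        KEEP.OUT.ATTRS = FALSE)
  pcc <- numeric(nrow(combos)); nerr <- integer(nrow(combos))
  for (k in seq_len(nrow(combos))) {
    cb <- combos[k, ]
    P <- vapply(summaries, function(s)
      mean(apply_criteria_post_hoc(s, cb$min_contacts, cb$min_pct,
                                   cb$max_rmsd, cb$max_ifd,
                                   cb$max_energy)), numeric(1))
    if (max(P) - min(P) <= 0) {
      pcc[k] <- NA_real_; nerr[k] <- NA_integer_
      next
    }
    kon <- probability_to_rate(P, rate_model_from_probs(P, kon_min, N))
    lk <- log10(kon)
    if (stats::sd(lk) == 0 || stats::sd(log10(kon_exp)) == 0) {
      pcc[k] <- NA_real_; nerr[k] <- NA_integer_
      next
    }
    pcc[k] <- stats::cor(lk, log10(kon_exp))
    nerr[k] <- log_ratio_errors(kon, kon_exp)$n_errors
  }
  table <- cbind(combos, pcc = pcc, n_errors = nerr)
  best <- if (all(is.na(pcc))) NULL else
    table[which.max(pcc), , drop = FALSE]
  list(table = table, best = best)
}

#' Read a benchmark manifest
#'
#' Tab-separated with header columns `complex_id`, `structure`,
#' `receptor_chains`, `ligand_chains`, `kon_exp`, `ionic_strength`
#' (chain groups as comma-separated chain IDs; ionic strength in mol/L,
#' NA allowed). Structure paths are resolved relative to the manifest's
#' directory.
#'
#' @param path manifest file path.
#' @return data.frame with one row per complex and a `xi` column (Debye
#'   length from the ionic strength where given).
#' @export
read_benchmark_manifest <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  need <- c("complex_id", "structure", "receptor_chains", "ligand_chains",
            "kon_exp", "ionic_strength")
  if (!all(need %in% names(df)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  stopifnot(all(df$kon_exp > 0))
  df$structure <- file.path(dirname(path), df$structure)
  df$xi <- ifelse(is.na(df$ionic_strength), NA_real_,
                  3.04 / sqrt(df$ionic_strength))
  df
}
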
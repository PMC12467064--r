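# Trade-Off Score: logistic compression of the parameter-count variation
# combined with the accuracy delta, for cost/performance model selection
# against a reference architecture.

#' Accuracy delta
#'
#' Candidate minus reference accuracy, in percentage points. Positive values
#' are a performance profit, negative a cost.
#'
#' @param Ac,Ar candidate and reference accuracies, percent.
#' @return `Ac - Ar`.
#' @export
accuracy_delta <- function(Ac, Ar) {
  stopifnot(all(Ac >= 0 & Ac <= 100), all(Ar >= 0 & Ar <= 100))
  Ac - Ar
}

#' Parameter variation
#'
#' Percent change in learnable-parameter count of the candidate relative to
#' the reference. Negative values (fewer parameters) are a profit.
#'
#' @param Pc,Pr candidate and reference learnable-parameter counts.
#' @return `100 * (Pc - Pr) / Pr`.
#' @export
parameters_variation <- function(Pc, Pr) {
  if (any(Pr <= 0)) {
    abort("reference parameter count must be positive", class = "gaitphase_config_error")
  }
  100 * (Pc - Pr) / Pr
}

#' Logistic compression of the parameter variation
#'
#' Maps the unbounded percent variation `Pv` into `(-L, L)` with slope `alpha`:
#' `Pvc = 2L / (1 + exp(alpha * Pv)) - L`. A parameter reduction (negative
#' `Pv`) yields a positive compressed cost, saturating at `+L`.
#'
#' @param Pv parameter variation, percent.
#' @param L boundary constant.
#' @param alpha logistic slope.
#' @return The compressed parameter-variation score.
#' @export
pvc <- function(Pv, L = 1, alpha = 0.05) {
  if (L <= 0 || alpha <= 0) {
    abort("L and alpha must be positive", class = "gaitphase_config_error")
  }
  2 * L / (1 + exp(alpha * Pv)) - L
}

#' Trade-Off Score of a candidate against a reference model
#'
#' `TOS = (Ad + Pvc) / (2L)`, combining the accuracy delta `Ad = Ac - Ar`
#' (percentage points) with the logistically compressed parameter variation.
#' The score is 0 when a model is compared with itself, positive when the
#' candidate trades parameters for accuracy favourably, and lies in
#' \[-1, 1\] provided `|Ad| <= 1` (a warning is raised otherwise, since the
#' normalization assumes accuracy deltas within one percentage point).
#' Candidates whose accuracy loss exceeds the floor (`Ad < ad_floor`,
#' default -1%) are excluded outright.
#'
#' @param Ac,Ar candidate and reference accuracies, percent.
#' @param Pc,Pr candidate and reference learnable-parameter counts.
#' @param L boundary constant.
#' @param alpha logistic slope.
#' @param ad_floor minimum allowed accuracy delta, percent.
#' @return A `tos_result`: list with `Ad`, `Pv`, `Pvc`, `tos` and `excluded`.
#' @export
tos <- function(Ac, Ar, Pc, Pr, L = 1, alpha = 0.05, ad_floor = -1) {
  Ad <- accuracy_delta(Ac, Ar)
  Pv <- parameters_variation(Pc, Pr)
  Pvc_ <- pvc(Pv, L = L, alpha = alpha)
  excluded <- Ad < ad_floor
  score <- if (excluded) NA_real_ else (Ad + Pvc_) / (2 * L)
  if (!excluded && abs(Ad) > 1) {
    warn("accuracy delta exceeds 1 percentage point; TOS may leave [-1, 1]")
  }
  structure(list(Ad = Ad, Pv = Pv, Pvc = Pvc_, tos = score,
                 excluded = excluded, L = L, alpha = alpha),
            class = "tos_result")
}

#' @export
print.tos_result <- function(x, ...) {
  if (x$excluded) {
    cat(sprintf("<tos_result> excluded (Ad = %.2f%% below floor)\n", x$Ad))
  } else {
    cat(sprintf("<tos_result> TOS %.3f (Ad %.2f%%, Pv %.2f%%, Pvc %.3f)\n",
                x$tos, x$Ad, x$Pv, x$Pvc))
  }
  invisible(x)
}

#' @export
tidy.tos_result <- function(x, ...) {
  tibble::tibble(Ad = x$Ad, Pv = x$Pv, Pvc = x$Pvc, tos = x$tos,
                 excluded = x$excluded)
}

# reporting convention: two decimals, half away from zero
round_half_away <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

#' Rank candidate models by Trade-Off Score
#'
#' Computes the TOS of every candidate against the reference, drops
#' candidates below the accuracy floor, and sorts the remainder by
#' descending score (ties broken toward the smaller parameter count, in
#' keeping with the metric's complexity-reduction intent).
#'
#' @param candidates data frame with columns `name`, `accuracy` (percent) and
#'   `n_parameters`.
#' @param reference list or one-row data frame with `accuracy` and
#'   `n_parameters` of the reference model.
#' @param L,alpha,ad_floor see [tos()].
#' @return Tibble of ranked candidates with `Ad`, `Pv`, `Pvc`, `tos` and
#'   `tos_2dp` (the two-decimal reporting value).
#' @export
rank_candidates <- function(candidates, reference, L = 1, alpha = 0.05,
                            ad_floor = -1) {
  if (!nrow(candidates)) abort("no candidates", class = "gaitphase_data_error")
  res <- purrr::map_dfr(seq_len(nrow(candidates)), function(i) {
    r <- suppressWarnings(
      tos(candidates$accuracy[i], reference$accuracy,
          candidates$n_parameters[i], reference$n_parameters,
          L = L, alpha = alpha, ad_floor = ad_floor))
    tibble::tibble(name = candidates$name[i],
                   accuracy = candidates$accuracy[i],
                   n_parameters = candidates$n_parameters[i],
                   Ad = r$Ad, Pv = r$Pv, Pvc = r$Pvc, tos = r$tos,
                   excluded = r$excluded)
  })
  res <- dplyr::filter(res, !.data$excluded)
  res <- dplyr::arrange(res, dplyr::desc(.data$tos), .data$n_parameters)
  res$tos_2dp <- round_half_away(res$tos, 2)
  res
}

#' Sensitivity of the TOS winner to the logistic slope
#'
#' Re-ranks the candidates (and the reference, which scores 0 by definition)
#' for each value of `alpha`. Small slopes weight parameter savings weakly,
#' so a candidate must match the reference's accuracy almost exactly to win;
#' larger slopes reward complexity reduction more aggressively.
#'
#' @param candidates,reference as in [rank_candidates()]; `reference` should
#'   carry a `name` (default "reference").
#' @param alphas slope values to test.
#' @param L,ad_floor see [tos()].
#' @return Tibble with one row per `alpha`: the winning model's name, TOS,
#'   and whether the reference retained the best trade-off.
#' @export
alpha_sensitivity <- function(candidates, reference,
                              alphas = c(0.001, 0.005, 0.01, 0.05),
                              L = 1, ad_floor = -1) {
  ref_name <- if (!is.null(reference$name)) reference$name else "reference"
  purrr::map_dfr(alphas, function(a) {
    ranked <- rank_candidates(candidates, reference, L = L, alpha = a,
                              ad_floor = ad_floor)
    # the reference scores 0 against itself; it wins if no candidate is positive
    if (nrow(ranked) && ranked$tos[1] > 0) {
      tibble::tibble(alpha = a, winner = ranked$name[1],
                     tos = ranked$tos[1], reference_wins = FALSE)
    } else {
      tibble::tibble(alpha = a, winner = ref_name, tos = 0,
                     reference_wins = TRUE)
    }
  })
}
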
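# Interpretation of the sparse equations: per-term contribution dynamics,
# growth/loss sign logic, and ranking of contributors over bloom growth
# windows.

#' Per-term contribution time series
#'
#' For every active coefficient, the product `c_i * f_i(x(t), drivers(t))`
#' on the sample's day grid. Summing all terms of one equation reproduces
#' that equation's fitted derivative exactly.
#'
#' @param model a `sparse_model`.
#' @param sample the `derivative_sample` the contributions are evaluated on
#'   (must use the same library inputs).
#' @return long data frame: `day`, `equation`, `term`, `value`, plus the
#'   reconstruction matrix as attribute `fitted` (grid x 5).
#' @export
term_timeseries <- function(model, sample) {
  stopifnot(inherits(model, "sparse_model"), inherits(sample, "derivative_sample"))
  Theta <- evaluate_library(model$library, sample$X, sample$D)
  act <- which(model$coef != 0, arr.ind = TRUE)
  out <- do.call(rbind, lapply(seq_len(nrow(act)), function(k) {
    i <- act[k, 1]; j <- act[k, 2]
    data.frame(day = sample$t,
               equation = rownames(model$coef)[i],
               term = colnames(model$coef)[j],
               value = model$coef[i, j] * Theta[, j],
               stringsAsFactors = FALSE)
  }))
  fitted <- Theta %*% t(model$coef)
  colnames(fitted) <- rownames(model$coef)
  attr(out, "fitted") <- fitted
  out
}

#' Growth/loss classification of a term
#'
#' The overall effect of a `coefficient * basis function` product on the
#' chlorophyll derivative follows the sign product: matching signs (both
#' positive, or a negative coefficient multiplying a below-average, negative
#' basis value) act as growth; opposite signs as loss; a zero on either side
#' is neutral.
#'
#' @param coefficient_sign,basis_value_sign values in `-1, 0, 1` (or the
#'   strings `"-"`, `"0"`, `"+"`).
#' @return `"growth"`, `"loss"` or `"neutral"` (vectorized).
#' @export
#' @examples
#' classify_term(1, 1)    # growth
#' classify_term(-1, -1)  # growth
#' classify_term(1, -1)   # loss
classify_term <- function(coefficient_sign, basis_value_sign) {
  to_num <- function(s) {
    if (is.character(s)) s <- c("-" = -1, "0" = 0, "+" = 1)[s]
    sign(as.numeric(s))
  }
  p <- unname(to_num(coefficient_sign) * to_num(basis_value_sign))
  ifelse(p > 0, "growth", ifelse(p < 0, "loss", "neutral"))
}

#' Detect bloom growth windows
#'
#' Maximal contiguous runs of days where the chlorophyll z-score is positive
#' (above average) and its derivative is positive (increasing). Runs shorter
#' than `min_days` are discarded as numerical sign flicker.
#'
#' @param chla chlorophyll series on the day grid.
#' @param dchla its derivative on the same grid (by convention the fitted
#'   derivative of the sparse model, for internal consistency).
#' @param days day grid.
#' @param min_days minimum window length (days).
#' @return data frame with columns `start`, `end` (day-of-year, inclusive);
#'   zero rows if no window qualifies.
#' @export
detect_growth_windows <- function(chla, dchla, days = seq_along(chla),
                                  min_days = 5) {
  stopifnot(length(chla) == length(dchla), length(chla) == length(days))
  active <- chla > 0 & dchla > 0
  r <- rle(active)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  out <- data.frame(start = days[starts[keep]], end = days[ends[keep]])
  out <- out[out$end - out$start + 1 >= min_days, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Rank term contributions over growth windows
#'
#' Integrates each term's contribution series over every window
#' (trapezoidal rule on the day grid), splits terms by the sign of the
#' integral, and expresses each term's share as `|integral|` over the sum of
#' `|integral|` within its sign group. The strongest positive and negative
#' contributors are reported per window; a term within `tie_tol` of the top
#' proportion is listed alongside it.
#'
#' @param terms long data frame from [term_timeseries()], filtered to one
#'   equation (defaults to the chlorophyll equation if several are present).
#' @param windows data frame from [detect_growth_windows()].
#' @param equation equation name to rank (default `"chla"`).
#' @param tie_tol near-tie threshold on proportions.
#' @return object of class `contribution_ranking`: a list with one element
#'   per window, each containing `window`, `table` (term, integral, sign
#'   group, proportion) and `top_positive` / `top_negative` character
#'   vectors.
#' @export
rank_contributions <- function(terms, windows, equation = "chla",
                               tie_tol = 0.01) {
  stopifnot(nrow(windows) >= 1)
  terms <- terms[terms$equation == equation, , drop = FALSE]
  if (nrow(terms) == 0) stop("no terms for equation '", equation, "'")
  out <- lapply(seq_len(nrow(windows)), function(w) {
    lo <- windows$start[w]; hi <- windows$end[w]
    tt <- sort(unique(terms$day[terms$day >= lo & terms$day <= hi]))
    ints <- vapply(split(terms, terms$term), function(df) {
      df <- df[df$day >= lo & df$day <= hi, ]
      df <- df[order(df$day), ]
      if (nrow(df) < 2) return(sum(df$value))
      pracma::trapz(df$day, df$value)
    }, numeric(1))
    tab <- data.frame(term = names(ints), integral = unname(ints),
                      stringsAsFactors = FALSE)
    tab$group <- ifelse(tab$integral > 0, "positive",
                        ifelse(tab$integral < 0, "negative", "zero"))
    tab$proportion <- NA_real_
    for (g in c("positive", "negative")) {
      idx <- tab$group == g
      tot <- sum(abs(tab$integral[idx]))
      if (tot > 0) tab$proportion[idx] <- abs(tab$integral[idx]) / tot
    }
    top_of <- function(g) {
      sub <- tab[tab$group == g & !is.na(tab$proportion), , drop = FALSE]
      if (nrow(sub) == 0) return(character(0))
      sub <- sub[order(-sub$proportion), , drop = FALSE]
      sub$term[sub$proportion >= sub$proportion[1] - tie_tol]
    }
    list(window = c(start = lo, end = hi),
         table = tab[order(-abs(tab$integral)), ],
         top_positive = top_of("positive"),
         top_negative = top_of("negative"))
  })
  structure(out, class = "contribution_ranking")
}

#' Export contribution rankings as a tidy table
#'
#' @param ranking a `contribution_ranking`.
#' @param pattern blooming-pattern label for the output rows.
#' @return data frame: pattern, window index, start, end, sign group, term,
#'   proportion.
#' @export
ranking_table <- function(ranking, pattern = NA_character_) {
  do.call(rbind, lapply(seq_along(ranking), function(w) {
    tab <- ranking[[w]]$table
    tab <- tab[tab$group %in% c("positive", "negative"), , drop = FALSE]
    if (nrow(tab) == 0) return(NULL)
    data.frame(pattern = pattern, window = w,
               start = ranking[[w]]$window["start"],
               end = ranking[[w]]$window["end"],
               group = tab$group, term = tab$term,
               proportion = tab$proportion, row.names = NULL)
  }))
}
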
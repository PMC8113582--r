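# Exotic dominance of community biomass versus the planted expectation.

#' Proportion of mesocosm biomass contributed by exotic plants
#'
#' Realised exotic share of plant biomass per mesocosm, using alive plants
#' only (dead plants are excluded from biomass analyses).
#'
#' @param outcomes Plant outcome table with `mesocosm_id`, `provenance`,
#'   `alive`, `aboveground_biomass_g`, `belowground_biomass_g`.
#' @param partition `"total"` (default) uses above + below ground biomass,
#'   `"aboveground"` the aboveground part only.
#' @return Data frame `mesocosm_id`, `prop_exotic_biomass`; mesocosms whose
#'   alive plants carry zero biomass get `NA` with a warning.
#' @examples
#' o <- data.frame(mesocosm_id = "M1", provenance = c("exotic", "native"),
#'                 alive = TRUE, aboveground_biomass_g = c(20, 5),
#'                 belowground_biomass_g = c(10, 5))
#' exotic_biomass_proportion(o)$prop_exotic_biomass  # 30 / 40
#' @export
exotic_biomass_proportion <- function(outcomes,
                                      partition = c("total", "aboveground")) {
  partition <- match.arg(partition)
  .assert_columns(outcomes, c("mesocosm_id", "provenance", "alive",
                              "aboveground_biomass_g",
                              "belowground_biomass_g"), "outcomes")
  x <- outcomes[outcomes$alive, ]
  x$biomass <- if (partition == "total")
    x$aboveground_biomass_g + x$belowground_biomass_g
  else x$aboveground_biomass_g
  tot <- tapply(x$biomass, x$mesocosm_id, sum)
  exo <- tapply(x$biomass * (x$provenance == "exotic"), x$mesocosm_id, sum)
  out <- data.frame(mesocosm_id = names(tot),
                    prop_exotic_biomass = ifelse(tot > 0,
                                                 as.numeric(exo / tot),
                                                 NA_real_),
                    stringsAsFactors = FALSE)
  if (anyNA(out$prop_exotic_biomass))
    warning(sum(is.na(out$prop_exotic_biomass)),
            " mesocosm(s) with zero total biomass; proportion set to NA")
  out <- out[order(out$mesocosm_id), ]
  rownames(out) <- NULL
  out
}

#' Exotic dominance versus the planted proportion, with confidence intervals
#'
#' For each level of the planted exotic proportion (mixed communities only:
#' 0 and 1 are excluded, since the realised proportion is then constrained)
#' crossed with the herbivore treatment, estimates the group mean realised
#' exotic biomass proportion and its two-sided 95% confidence interval, and
#' flags (i) whether the interval lies entirely above the planted expectation
#' (`exceeds_expected`) and (ii) whether the +Herbivore and -Herbivore
#' intervals overlap within a planted level (`overlaps_other_treatment`).
#'
#' @param proportions Output of [exotic_biomass_proportion()].
#' @param mesocosms Mesocosm design table with `mesocosm_id`,
#'   `herbivore_treatment`, `prop_exotic_planted`.
#' @param conf_level Confidence level (default 0.95).
#' @param method `"t"` (default, Student-t interval on the raw proportions)
#'   or `"bootstrap"` (percentile interval).
#' @param n_boot Bootstrap resamples when `method = "bootstrap"`.
#' @return Data frame of class `dominance_summary` with columns
#'   `prop_exotic_planted`, `herbivore_treatment`, `n`, `mean_realised_prop`,
#'   `ci_low`, `ci_high`, `expected`, `exceeds_expected`,
#'   `overlaps_other_treatment`. Groups with fewer than 2 mesocosms get `NA`
#'   intervals with a warning.
#' @export
dominance_ci_table <- function(proportions, mesocosms, conf_level = 0.95,
                               method = c("t", "bootstrap"), n_boot = 2000L) {
  method <- match.arg(method)
  .assert_columns(proportions, c("mesocosm_id", "prop_exotic_biomass"),
                  "proportions")
  .assert_columns(mesocosms, c("mesocosm_id", "herbivore_treatment",
                               "prop_exotic_planted"), "mesocosms")
  x <- merge(proportions, mesocosms, by = "mesocosm_id")
  x <- x[x$prop_exotic_planted > 0 & x$prop_exotic_planted < 1 &
           !is.na(x$prop_exotic_biomass), ]
  groups <- unique(x[, c("prop_exotic_planted", "herbivore_treatment")])
  groups <- groups[order(groups$prop_exotic_planted,
                         groups$herbivore_treatment), ]
  rows <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    v <- x$prop_exotic_biomass[x$prop_exotic_planted ==
                                 g$prop_exotic_planted &
                               x$herbivore_treatment ==
                                 g$herbivore_treatment]
    n <- length(v)
    m <- mean(v)
    if (n < 2L) {
      warning("dominance group with fewer than 2 mesocosms (planted = ",
              g$prop_exotic_planted, ", ", g$herbivore_treatment,
              "); no interval")
      ci <- c(NA_real_, NA_real_)
    } else if (method == "t") {
      se <- stats::sd(v) / sqrt(n)
      tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
      ci <- m + c(-1, 1) * tq * se
    } else {
      bm <- vapply(seq_len(n_boot),
                   function(b) mean(v[sample.int(n, n, replace = TRUE)]),
                   numeric(1))
      ci <- unname(stats::quantile(bm, c((1 - conf_level) / 2,
                                         1 - (1 - conf_level) / 2)))
    }
    data.frame(prop_exotic_planted = g$prop_exotic_planted,
               herbivore_treatment = g$herbivore_treatment,
               n = n, mean_realised_prop = m,
               ci_low = ci[1], ci_high = ci[2],
               expected = g$prop_exotic_planted,
               exceeds_expected = !is.na(ci[1]) &&
                 ci[1] > g$prop_exotic_planted,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$overlaps_other_treatment <- NA
  for (lev in unique(out$prop_exotic_planted)) {
    sel <- which(out$prop_exotic_planted == lev)
    if (length(sel) == 2L && !anyNA(out$ci_low[sel])) {
      overlap <- out$ci_low[sel[1]] <= out$ci_high[sel[2]] &&
        out$ci_low[sel[2]] <= out$ci_high[sel[1]]
      out$overlaps_other_treatment[sel] <- overlap
    }
  }
  rownames(out) <- NULL
  class(out) <- c("dominance_summary", class(out))
  out
}

#' @export
print.dominance_summary <- function(x, ...) {
  cat("Exotic dominance vs planted proportion (alive plants only)\n")
  print.data.frame(x, digits = 3, row.names = FALSE)
  invisible(x)
}
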
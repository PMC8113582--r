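# Potential for apparent competition (Muller et al. 1999) on quantitative
# plant-herbivore webs.

#' Pairwise potential for apparent competition
#'
#' For a plants x herbivores biomass matrix `alpha`, computes
#' `d[i, j] = sum_k (alpha[i, k] / sum_l alpha[i, l]) *
#'                  (alpha[j, k] / sum_m alpha[m, k])`,
#' the proportion of the herbivore biomass attacking plant `i` that is shared
#' with plant `j` -- the potential for plant `j` to exert apparent
#' competition on plant `i` through shared herbivores. Terms with a zero
#' denominator (plants carrying no herbivores, herbivore columns with no
#' hosts) contribute 0, so plants sharing no herbivores get `d = 0` and
#' zero-load plants give all-zero rows. For every plant with positive load,
#' `sum_j d[i, j]` (diagonal included) equals 1.
#'
#' @param x An `interaction_matrix` or a non-negative numeric matrix
#'   (plants in rows, herbivores in columns).
#' @return Square matrix `d` (receivers in rows, donors in columns), with
#'   plant ids as dimnames when available.
#' @examples
#' a <- matrix(c(2, 1, 0, 0, 1, 1), nrow = 3, byrow = TRUE,
#'             dimnames = list(c("A", "B", "C"), c("h1", "h2")))
#' pairwise_pac(a)["A", "B"]  # (2/2) * (1/3)
#' @export
pairwise_pac <- function(x) {
  alpha <- if (inherits(x, "interaction_matrix")) x$alpha else as.matrix(x)
  if (!is.numeric(alpha)) stop("alpha must be numeric", call. = FALSE)
  if (any(alpha < 0)) stop("alpha must be non-negative", call. = FALSE)
  rs <- rowSums(alpha)
  cs <- colSums(alpha)
  if (nrow(alpha) == 0L || ncol(alpha) == 0L) {
    d <- matrix(0, nrow(alpha), nrow(alpha),
                dimnames = list(rownames(alpha), rownames(alpha)))
    return(d)
  }
  # row shares of the focal plant's herbivore load; column shares of each
  # herbivore's biomass across plants; 0/0 := 0
  r <- alpha / ifelse(rs > 0, rs, 1)
  cshare <- sweep(alpha, 2, ifelse(cs > 0, cs, 1), "/")
  d <- r %*% t(cshare)
  dimnames(d) <- list(rownames(alpha), rownames(alpha))
  d
}

#' Community-level PAC aggregates per plant
#'
#' Sums pairwise PAC over heterospecific partners (the diagonal --
#' intraspecific PAC -- is excluded) and weights by herbivore biomass:
#' the potential to exert apparent competition on the community is weighted
#' by the focal plant's own herbivore biomass `B_i`, the potential to
#' receive it by the rest of the community's biomass `B_{-i}`. Because
#' `d[i, j]` is the effect of donor `j` on receiver `i`, exerted sums the
#' focal plant's column and received its row; `direction = "transposed"`
#' swaps the two readings.
#'
#' @param d Matrix from [pairwise_pac()].
#' @param x The `interaction_matrix` (or alpha matrix) `d` was computed from.
#' @param direction `"muller"` (default; exerted = column sums of `d`) or
#'   `"transposed"` (exerted = row sums).
#' @return An object of class `pac_result`: list with `mesocosm_id`, `d`,
#'   and per-plant vectors `pac_exerted`, `pac_received`, `focal_biomass`
#'   (`B_i`), `other_biomass` (`B_{-i}`), plus the unweighted sums
#'   `share_exerted`, `share_received`.
#' @examples
#' a <- matrix(c(1, 1), nrow = 2, dimnames = list(c("p1", "p2"), "h"))
#' aggregate_pac(pairwise_pac(a), a)$pac_exerted  # 0.5, 0.5
#' @export
aggregate_pac <- function(d, x, direction = c("muller", "transposed")) {
  direction <- match.arg(direction)
  alpha <- if (inherits(x, "interaction_matrix")) x$alpha else as.matrix(x)
  if (nrow(d) != nrow(alpha) || ncol(d) != nrow(alpha))
    stop("d must be a square matrix with one row per plant in alpha",
         call. = FALSE)
  B <- rowSums(alpha)
  B_other <- sum(B) - B
  off_row <- rowSums(d) - diag(d)   # sum_{j != i} d_ij
  off_col <- colSums(d) - diag(d)   # sum_{j != i} d_ji
  if (direction == "muller") {
    exerted_share <- off_col
    received_share <- off_row
  } else {
    exerted_share <- off_row
    received_share <- off_col
  }
  structure(list(mesocosm_id = if (inherits(x, "interaction_matrix"))
                   x$mesocosm_id else NA_character_,
                 d = d,
                 pac_exerted = exerted_share * B,
                 pac_received = received_share * B_other,
                 share_exerted = exerted_share,
                 share_received = received_share,
                 focal_biomass = B,
                 other_biomass = B_other,
                 direction = direction),
            class = "pac_result")
}

#' @export
print.pac_result <- function(x, ...) {
  cat(sprintf("PAC result (%s): %d plants, mean exerted %.4g, mean received %.4g\n",
              x$mesocosm_id, length(x$pac_exerted), mean(x$pac_exerted),
              mean(x$pac_received)))
  invisible(x)
}

#' Compute PAC for every mesocosm
#'
#' @param imats Named list from [interaction_matrices()].
#' @inheritParams aggregate_pac
#' @return Named list of `pac_result` objects.
#' @export
compute_pac <- function(imats, direction = c("muller", "transposed")) {
  direction <- match.arg(direction)
  lapply(imats, function(im) aggregate_pac(pairwise_pac(im), im,
                                           direction = direction))
}

#' Long-format PAC table across mesocosms
#'
#' @param pac_results Named list of `pac_result` objects (see
#'   [compute_pac()]).
#' @param imats The matching list of interaction matrices (for species and
#'   provenance labels).
#' @param design Optional `mesocosm_design` (or mesocosm table) to attach
#'   treatment columns.
#' @return Data frame `mesocosm_id`, `plant_id`, `plant_species`,
#'   `provenance`, `pac_exerted`, `pac_received`, `B_i`, `B_minus_i`
#'   (+ treatments when `design` is given).
#' @export
pac_table <- function(pac_results, imats, design = NULL) {
  rows <- lapply(names(pac_results), function(m) {
    pr <- pac_results[[m]]
    im <- imats[[m]]
    data.frame(mesocosm_id = m,
               plant_id = names(pr$pac_exerted),
               plant_species = unname(im$plant_species[names(pr$pac_exerted)]),
               provenance = if (!is.null(im$plant_provenance))
                 unname(im$plant_provenance[names(pr$pac_exerted)])
                 else NA_character_,
               pac_exerted = unname(pr$pac_exerted),
               pac_received = unname(pr$pac_received),
               B_i = unname(pr$focal_biomass),
               B_minus_i = unname(pr$other_biomass),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(design)) {
    meso <- if (inherits(design, "mesocosm_design")) design$mesocosms else design
    out <- merge(out, meso[, c("mesocosm_id", "herbivore_treatment",
                               "soil_treatment")],
                 by = "mesocosm_id", sort = FALSE)
  }
  out <- out[order(out$mesocosm_id, out$plant_id), ]
  rownames(out) <- NULL
  out
}

#' Summarise PAC by provenance and treatment
#'
#' Group means and standard errors of log-transformed PAC (the conventional
#' scale for these right-skewed quantities) by plant provenance, herbivore
#' and soil treatment. Zeroes are handled with a half-minimum offset:
#' `log(x + min(x[x > 0]) / 2)`; the offset used is recorded in the output
#' attributes. Raw-scale means are reported alongside.
#'
#' @param pac_df Output of [pac_table()] including treatment columns.
#' @return Data frame with one row per provenance x herbivore x soil group
#'   and columns `n`, `mean_exerted`, `mean_received` (raw scale),
#'   `mean_log_exerted`, `se_log_exerted`, `mean_log_received`,
#'   `se_log_received`; empty groups give an NA row with a warning.
#' @export
pac_treatment_summary <- function(pac_df) {
  .assert_columns(pac_df, c("provenance", "herbivore_treatment",
                            "soil_treatment", "pac_exerted", "pac_received"),
                  "pac_df")
  offset_e <- .log_offset(pac_df$pac_exerted)
  offset_r <- .log_offset(pac_df$pac_received)
  groups <- expand.grid(provenance = sort(unique(pac_df$provenance)),
                        herbivore_treatment =
                          sort(unique(pac_df$herbivore_treatment)),
                        soil_treatment = sort(unique(pac_df$soil_treatment)),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sel <- pac_df$provenance == g$provenance &
      pac_df$herbivore_treatment == g$herbivore_treatment &
      pac_df$soil_treatment == g$soil_treatment
    n <- sum(sel)
    if (n == 0L) {
      warning("empty PAC summary group: ",
              paste(unlist(g), collapse = " / "))
      return(cbind(g, n = 0L, mean_exerted = NA_real_,
                   mean_received = NA_real_, mean_log_exerted = NA_real_,
                   se_log_exerted = NA_real_, mean_log_received = NA_real_,
                   se_log_received = NA_real_))
    }
    # with no positive values anywhere the log scale is undefined
    le <- if (is.na(offset_e)) rep(NA_real_, n)
          else log(pac_df$pac_exerted[sel] + offset_e)
    lr <- if (is.na(offset_r)) rep(NA_real_, n)
          else log(pac_df$pac_received[sel] + offset_r)
    cbind(g, n = n,
          mean_exerted = mean(pac_df$pac_exerted[sel]),
          mean_received = mean(pac_df$pac_received[sel]),
          mean_log_exerted = mean(le),
          se_log_exerted = stats::sd(le) / sqrt(n),
          mean_log_received = mean(lr),
          se_log_received = stats::sd(lr) / sqrt(n))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "log_offset_exerted") <- offset_e
  attr(out, "log_offset_received") <- offset_r
  out
}

# Half the smallest positive value when zeros are present, 0 when all values
# are positive, NA when none are (log scale undefined).

#' @keywords internal
#' @noRd
.log_offset <- function(x) {
  pos <- x[x > 0]
  if (length(pos) == 0L) return(NA_real_)
  if (any(x == 0)) min(pos) / 2 else 0
}
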
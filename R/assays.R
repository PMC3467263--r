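#' Relative expression by the delta-delta-Ct method
#'
#' Per sample, dCt = Ct(target) - Ct(housekeeping); ddCt = dCt - mean dCt of
#' the control group; fold = 2^(-ddCt). Normalisation fixes the control
#' group's *mean* dCt as the reference, so individual control folds are 1
#' only when all control dCts coincide. Technical replicates (several Ct
#' rows for the same sample and gene) are averaged first.
#'
#' @param cts data.frame with columns `sample_id`, `group`, `gene`, `ct`
#'   (cycles, > 0).
#' @param target Target gene label (e.g. `"NDRG2"`).
#' @param housekeeping Housekeeping gene label (default `"TBP"`).
#' @param control_group Label of the reference group (e.g. `"DMSO"`).
#' @return List with `samples` (sample_id, group, dct, ddct, fold) and
#'   `groups` (group, n, mean_fold, sem; SEM uses the n-1 variance).
#' @export
ddct_fold <- function(cts, target, housekeeping = "TBP", control_group) {
  stopifnot(all(c("sample_id", "group", "gene", "ct") %in% names(cts)),
            all(cts$ct > 0))
  per_sample <- function(gene) {
    sub <- cts[cts$gene == gene, , drop = FALSE]
    tapply(sub$ct, sub$sample_id, mean)
  }
  ct_t <- per_sample(target)
  ct_h <- per_sample(housekeeping)
  samples <- unique(cts[, c("sample_id", "group")])
  missing_h <- setdiff(names(ct_t), names(ct_h))
  if (length(missing_h))
    stop("missing housekeeping Ct for sample(s): ", paste(missing_h, collapse = ", "))
  samples <- samples[samples$sample_id %in% names(ct_t), , drop = FALSE]
  if (!control_group %in% samples$group) stop("control group '", control_group, "' is empty")
  dct <- ct_t[samples$sample_id] - ct_h[samples$sample_id]
  ref <- mean(dct[samples$group == control_group])
  ddct <- dct - ref
  fold <- 2^(-ddct)
  samples <- data.frame(sample_id = samples$sample_id, group = samples$group,
                        dct = as.numeric(dct), ddct = as.numeric(ddct),
                        fold = as.numeric(fold), stringsAsFactors = FALSE)
  groups <- do.call(rbind, lapply(split(samples, samples$group), function(g)
    data.frame(group = g$group[1L], n = nrow(g), mean_fold = mean(g$fold),
               sem = stats::sd(g$fold) / sqrt(nrow(g)), stringsAsFactors = FALSE)))
  rownames(groups) <- NULL
  list(samples = samples, groups = groups)
}

#' Relative luciferase activity and fold induction
#'
#' RLA per well = firefly / Renilla; fold induction = mean RLA of the
#' treated condition divided by mean RLA of the control condition.
#'
#' @param wells data.frame with columns `well_id`, `condition`, `firefly`
#'   (>= 0), `renilla` (> 0).
#' @param treated,control Condition labels (e.g. agonist vs `"DMSO"`).
#' @return List with `fold` (scalar) and `rla` (per-well data.frame).
#' @export
rla_fold <- function(wells, treated, control) {
  stopifnot(all(c("well_id", "condition", "firefly", "renilla") %in% names(wells)),
            all(wells$firefly >= 0))
  if (any(wells$renilla <= 0)) stop("Renilla signal must be positive (normalisation denominator)")
  if (!treated %in% wells$condition) stop("no wells with condition '", treated, "'")
  if (!control %in% wells$condition) stop("no wells with condition '", control, "'")
  rla <- data.frame(well_id = wells$well_id, condition = wells$condition,
                    rla = wells$firefly / wells$renilla, stringsAsFactors = FALSE)
  fold <- mean(rla$rla[rla$condition == treated]) / mean(rla$rla[rla$condition == control])
  list(fold = fold, rla = rla)
}

#' In-silico PCR product sizing
#'
#' Finds every exact match of the forward primer on the template and every
#' downstream exact match of the reverse complement of the reverse primer,
#' and reports each resulting product span inclusive of both primer
#' footprints. Exact matching only; no product is an empty result, not an
#' error.
#'
#' @param template Nucleotide string (upper-cased internally).
#' @param forward,reverse Primer sequences as synthesised (5'->3'); may also
#'   be given as a single named vector `c(forward=, reverse=)` in `forward`.
#' @return data.frame with 0-based half-open `start`/`end` and `length` (bp),
#'   one row per product, sorted by start then length.
#' @export
#' @examples
#' tpl <- paste0("AAGGAACC", "ACGTACGT", revcomp("TTGGCCAA"))
#' insilico_pcr(tpl, "AAGGAACC", "TTGGCCAA")$length  # 24
insilico_pcr <- function(template, forward, reverse = NULL) {
  if (is.null(reverse)) {
    stopifnot(all(c("forward", "reverse") %in% names(forward)))
    reverse <- forward[["reverse"]]; forward <- forward[["forward"]]
  }
  stopifnot(nzchar(forward), nzchar(reverse),
            grepl("^[ACGT]+$", forward), grepl("^[ACGT]+$", reverse))
  template <- toupper(template)
  find_all <- function(needle) {  # 0-based starts of exact occurrences
    m <- gregexpr(needle, template, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }
  f_starts <- find_all(forward)
  r_starts <- find_all(revcomp(reverse))
  len_f <- nchar(forward); len_r <- nchar(reverse)
  prods <- list()
  for (fs in f_starts) for (rs in r_starts) {
    if (rs >= fs + len_f) {
      prods[[length(prods) + 1L]] <-
        data.frame(start = fs, end = rs + len_r, length = rs + len_r - fs)
    }
  }
  out <- if (length(prods)) do.call(rbind, prods)
         else data.frame(start = integer(0), end = integer(0), length = integer(0))
  out <- out[order(out$start, out$length), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Map a p value to the significance-star convention
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, `ns` otherwise.
#'
#' @param p p value(s) in \[0, 1\].
#' @return Character vector over \{"ns", "*", "**", "***"\}.
#' @export
significance_stars <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Two-sided unpaired t-test with significance stars
#'
#' Classical pooled-variance (Student) two-sample test by default, Welch's
#' unequal-variance form behind `welch = TRUE`. Degenerate zero-variance
#' input: equal means give t = 0, p = 1; unequal means leave the statistic
#' undefined and raise an error.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @param welch Use the Welch correction instead of pooling (default FALSE).
#' @return List with `statistic`, `df`, `p_value`, `stars`.
#' @export
unpaired_t <- function(a, b, welch = FALSE) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) >= 2L, length(b) >= 2L)
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (length(a) + length(b) - 2L)
  if (pooled_var == 0) {
    if (mean(a) == mean(b))
      return(list(statistic = 0, df = length(a) + length(b) - 2L, p_value = 1,
                  stars = "ns"))
    stop("zero within-group variance with unequal means: t statistic undefined")
  }
  tt <- stats::t.test(a, b, var.equal = !welch)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, stars = significance_stars(tt$p.value))
}
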
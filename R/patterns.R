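BASES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of a plain nucleotide string
#'
#' Complements A/C/G/T (and leaves N as N) and reverses. Used throughout on
#' plain character sequences; FASTA-level work goes through Biostrings.
#'
#' @param x A single character string (A/C/G/T/N, upper case).
#' @return The reverse-complemented string.
#' @export
#' @examples
#' revcomp("GGGTTAGTGACCC")  # self-reverse-complementary IR1 element
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = ""))
}

#' Parse a bracket-form degenerate consensus
#'
#' Parses strings such as `"[GA]GGT[TC]A"` into an ordered list of
#' allowed-base sets, one per consensus position. `N` maps to the full set
#' \{A,C,G,T\}; `[...]` encloses an explicit alternative set.
#'
#' @param text Consensus text using A/C/G/T/N and bracketed alternatives.
#' @return An object of class `iupac_pattern`: list with `sets` (list of
#'   character vectors) and `length`.
#' @export
#' @examples
#' p <- parse_halfsite("[GA]GGT[TC]A")
#' p$length  # 6
parse_halfsite <- function(text) {
  stopifnot(is.character(text), length(text) == 1L, !is.na(text))
  chars <- strsplit(toupper(text), "", fixed = TRUE)[[1L]]
  sets <- list()
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "[") {
      close <- which(chars == "]" & seq_along(chars) > i)
      if (length(close) == 0L)
        stop("unbalanced '[' at position ", i, " of '", text, "'")
      close <- close[1L]
      alt <- chars[seq(i + 1L, length.out = close - i - 1L)]
      if (length(alt) == 0L)
        stop("empty alternative set at position ", i, " of '", text, "'")
      if (!all(alt %in% BASES))
        stop("illegal character in alternative set at position ", i, " of '", text, "'")
      sets[[length(sets) + 1L]] <- unique(alt)
      i <- close + 1L
    } else if (ch == "]") {
      stop("unbalanced ']' at position ", i, " of '", text, "'")
    } else if (ch == "N") {
      sets[[length(sets) + 1L]] <- BASES
      i <- i + 1L
    } else if (ch %in% BASES) {
      sets[[length(sets) + 1L]] <- ch
      i <- i + 1L
    } else {
      stop("illegal character '", ch, "' at position ", i, " of '", text, "'")
    }
  }
  if (length(sets) == 0L) stop("empty pattern: '", text, "'")
  new_iupac_pattern(sets)
}

new_iupac_pattern <- function(sets) {
  stopifnot(length(sets) >= 1L, all(vapply(sets, length, 1L) >= 1L))
  sets <- lapply(sets, function(s) {
    s <- unique(s)
    stopifnot(all(s %in% BASES))
    s[order(match(s, BASES))]
  })
  structure(list(sets = sets, length = length(sets)), class = "iupac_pattern")
}

#' Bracket text form of a degenerate pattern
#'
#' Inverse of [parse_halfsite()] up to set ordering: singleton sets print as
#' the base, the full set prints as `N`, others as `[..]` in A<C<G<T order.
#'
#' @param pattern An `iupac_pattern`.
#' @return A single string.
#' @export
bracket_form <- function(pattern) {
  stopifnot(inherits(pattern, "iupac_pattern"))
  paste(vapply(pattern$sets, function(s) {
    if (length(s) == 1L) s
    else if (length(s) == 4L) "N"
    else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

#' @export
print.iupac_pattern <- function(x, ...) {
  cat("<iupac_pattern> ", bracket_form(x), " (", x$length, " positions)\n", sep = "")
  invisible(x)
}

#' @export
print.response_element <- function(x, ...) {
  cat("<response_element> ", x$geometry, x$spacer, ": ", bracket_form(x$full),
      if (x$self_rc) "  [self-RC]" else "", "\n", sep = "")
  invisible(x)
}

rc_sets <- function(sets) {
  rev(lapply(sets, function(s) {
    s <- unname(COMPLEMENT[s])
    s[order(match(s, BASES))]
  }))
}

sets_equal <- function(a, b) {
  length(a) == length(b) &&
    all(mapply(function(x, y) length(x) == length(y) && setequal(x, y), a, b))
}

#' Compile a half-site into a full response-element pattern
#'
#' Arranges two copies of a half-site consensus as an inverted (IR), direct
#' (DR) or everted (ER) repeat with `spacer` unconstrained positions between
#' them. For IR the right half is the reverse complement of the left (the
#' IR1 case: half `[GA]GGT[TC]A` yields right half `T[AG]ACC[TC]`); for DR
#' both halves read the same; for ER the left half is the reverse complement
#' and the right is direct. The `self_rc` flag records whether the full
#' pattern equals its own reverse-complement mirror, in which case a match
#' is a single physical site visible identically from either strand.
#'
#' @param half An `iupac_pattern` (or bracket text, parsed on the fly).
#' @param geometry `"IR"`, `"DR"` or `"ER"`.
#' @param spacer Non-negative integer count of unconstrained positions.
#' @return An object of class `response_element` with fields `left`,
#'   `right`, `spacer`, `full`, `geometry`, `spacer_idx` and `self_rc`.
#' @export
#' @examples
#' ir1 <- compile_element("[GA]GGT[TC]A", "IR", 1)
#' bracket_form(ir1$full)  # "[AG]GGT[CT]ANT[AG]ACC[CT]"
compile_element <- function(half, geometry = c("IR", "DR", "ER"), spacer = 1L) {
  if (is.character(half)) half <- parse_halfsite(half)
  stopifnot(inherits(half, "iupac_pattern"))
  geometry <- match.arg(geometry)
  spacer <- as.integer(spacer)
  stopifnot(length(spacer) == 1L, !is.na(spacer), spacer >= 0L)

  rc_half <- rc_sets(half$sets)
  halves <- switch(geometry,
    IR = list(left = half$sets, right = rc_half),
    DR = list(left = half$sets, right = half$sets),
    ER = list(left = rc_half, right = half$sets))
  spacer_sets <- rep(list(BASES), spacer)
  full_sets <- c(halves$left, spacer_sets, halves$right)
  full <- new_iupac_pattern(full_sets)
  spacer_idx <- if (spacer > 0L) seq(half$length + 1L, length.out = spacer) else integer(0)
  self_rc <- sets_equal(full$sets, rc_sets(full$sets))
  structure(list(
    left = new_iupac_pattern(halves$left),
    right = new_iupac_pattern(halves$right),
    spacer = spacer,
    geometry = geometry,
    full = full,
    spacer_idx = spacer_idx,
    self_rc = self_rc
  ), class = "response_element")
}

#' The canonical IR1 matcher for FXR response elements
#'
#' Convenience constructor for the 13-position IR1 full site built from the
#' FXR half-site consensus `[GA]GGT[TC]A` with a 1 bp spacer.
#'
#' @return A `response_element`.
#' @export
ir1_element <- function() compile_element(fxre_halfsite, "IR", 1L)

# logical allowed-lookup per pattern position, indexed by base 1..4 (A,C,G,T)
allowed_lookup <- function(element) {
  lapply(seq_len(element$full$length), function(j) {
    if (j %in% element$spacer_idx) rep(TRUE, 4L)
    else BASES %in% element$full$sets[[j]]
  })
}

seq_to_int <- function(seq) match(strsplit(toupper(seq), "", fixed = TRUE)[[1L]], BASES)

#' Count mismatches of a window against a response element
#'
#' Compares `seq[pos .. pos+L-1]` (0-based `pos`) position-wise against the
#' element's full pattern. Spacer positions never contribute; characters
#' outside A/C/G/T (e.g. N) count as mismatches at constrained positions.
#'
#' @param seq Nucleotide string.
#' @param pos 0-based offset of the window start.
#' @param element A `response_element`.
#' @return Integer mismatch count.
#' @export
#' @examples
#' mismatches_at("GGGTTAGTGACCC", 0, ir1_element())  # 0
#' mismatches_at("AGGTTGATGACCC", 0, ir1_element())  # 1
mismatches_at <- function(seq, pos, element) {
  stopifnot(inherits(element, "response_element"))
  L <- element$full$length
  n <- nchar(seq)
  pos <- as.integer(pos)
  if (pos < 0L || pos + L > n)
    stop("window [", pos, ", ", pos + L, ") out of range for sequence of length ", n)
  si <- seq_to_int(substr(toupper(seq), pos + 1L, pos + L))
  allowed <- allowed_lookup(element)
  mm <- 0L
  for (j in seq_len(L)) {
    if (j %in% element$spacer_idx) next
    b <- si[j]
    if (is.na(b) || !allowed[[j]][b]) mm <- mm + 1L
  }
  mm
}

# vectorized mismatch profile over every window start of an integer-coded
# sequence; returns integer vector of length n - L + 1 (empty if n < L)
mismatch_profile <- function(si, element) {
  L <- element$full$length
  n <- length(si)
  if (n < L) return(integer(0))
  nw <- n - L + 1L
  mm <- integer(nw)
  allowed <- allowed_lookup(element)
  constrained <- setdiff(seq_len(L), element$spacer_idx)
  for (j in constrained) {
    b <- si[j:(j + nw - 1L)]
    ok <- !is.na(b) & allowed[[j]][pmax(b, 1L)]
    ok[is.na(ok)] <- FALSE
    mm <- mm + !ok
  }
  mm
}

#' Scan a sequence for response-element matches under a mismatch budget
#'
#' Reports every window whose constrained positions deviate from the
#' pattern's allowed sets at no more than `max_mm` positions. With
#' `strands = "both"` and a self-reverse-complementary pattern each physical
#' site is reported once, canonicalised to the plus strand; for non-self-RC
#' patterns minus-strand matches are reported with `strand == "-"` and a
#' plus-strand `start`. Overlapping hits are all reported. Coordinates are
#' 0-based half-open in `start`/`end`; 1-based inclusive `start1`/`end1`
#' columns are carried for display.
#'
#' @param seq Nucleotide string (upper-cased internally).
#' @param element A `response_element`.
#' @param max_mm Mismatch budget (default 0, the strict consensus screen).
#' @param strands `"both"` (default) or `"plus"`.
#' @param seq_id Optional identifier copied into the result.
#' @return A data.frame with columns `seq_id`, `start`, `end`, `start1`,
#'   `end1`, `strand`, `length`, `mismatches`, `matched` (the plus-strand
#'   literal substring), sorted by `start`.
#' @export
#' @examples
#' hits <- scan_motif(ndrg2_re_wt, ir1_element(), max_mm = 1)
#' hits$start  # 15 and 32
scan_motif <- function(seq, element, max_mm = 0L, strands = c("both", "plus"),
                       seq_id = NA_character_) {
  stopifnot(inherits(element, "response_element"))
  strands <- match.arg(strands)
  max_mm <- as.integer(max_mm)
  stopifnot(max_mm >= 0L)
  seq <- toupper(seq)
  L <- element$full$length
  n <- nchar(seq)

  hit_rows <- function(starts0, mms, strand) {
    matched <- if (length(starts0)) substring(seq, starts0 + 1L, starts0 + L)
               else character(0)
    data.frame(
      seq_id = rep(seq_id, length(starts0)),
      start = starts0, end = starts0 + L,
      start1 = starts0 + 1L, end1 = starts0 + L,
      strand = rep(strand, length(starts0)),
      length = rep(L, length(starts0)),
      mismatches = mms,
      matched = matched,
      stringsAsFactors = FALSE)
  }

  if (n < L) return(hit_rows(integer(0), integer(0), character(0)))

  si <- seq_to_int(seq)
  mm_plus <- mismatch_profile(si, element)
  keep <- which(mm_plus <= max_mm)
  res <- hit_rows(keep - 1L, mm_plus[keep], "+")

  if (strands == "both" && !element$self_rc) {
    si_rc <- rev(5L - si)  # A<->T, C<->G on 1..4 coding; NA stays NA
    mm_minus <- mismatch_profile(si_rc, element)
    keep_rc <- which(mm_minus <= max_mm)
    starts0 <- n - L - (keep_rc - 1L)
    res <- rbind(res, hit_rows(starts0, mm_minus[keep_rc], "-"))
  }
  res[order(res$start, res$strand), , drop = FALSE]
}

#' Number of distinct exact words matching a pattern
#'
#' Product of the allowed-set sizes over all positions (spacer positions
#' contribute 4). For the IR1 full site this is 64.
#'
#' @param element A `response_element`.
#' @return Numeric word count.
#' @export
pattern_word_count <- function(element) {
  stopifnot(inherits(element, "response_element"))
  prod(vapply(element$full$sets, length, 1L))
}
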
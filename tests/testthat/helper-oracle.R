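# Independent naive scanning oracle: per-position, per-strand character
# comparison, sharing no code path with scan_motif()/mismatch_profile().

oracle_scan <- function(seq, element, max_mm, strands = "both") {
  sets <- element$full$sets
  L <- length(sets)
  spacer <- element$spacer_idx
  count_mm <- function(chars, i0) {
    mm <- 0L
    for (j in seq_len(L)) {
      if (j %in% spacer) next
      if (!(chars[i0 + j] %in% sets[[j]])) mm <- mm + 1L
    }
    mm
  }
  scan_one <- function(s) {
    chars <- strsplit(toupper(s), "", fixed = TRUE)[[1L]]
    n <- length(chars)
    starts <- integer(0); mms <- integer(0)
    if (n >= L) for (i0 in 0:(n - L)) {
      m <- count_mm(chars, i0)
      if (m <= max_mm) { starts <- c(starts, i0); mms <- c(mms, m) }
    }
    list(starts = starts, mms = mms)
  }
  plus <- scan_one(seq)
  res <- data.frame(start = plus$starts, strand = rep("+", length(plus$starts)),
                    mismatches = plus$mms, stringsAsFactors = FALSE)
  if (strands == "both" && !element$self_rc) {
    n <- nchar(seq)
    rc <- chartr("ACGTN", "TGCAN",
                 paste(rev(strsplit(toupper(seq), "", fixed = TRUE)[[1L]]), collapse = ""))
    minus <- scan_one(rc)
    res <- rbind(res, data.frame(start = n - L - minus$starts,
                                 strand = rep("-", length(minus$starts)),
                                 mismatches = minus$mms, stringsAsFactors = FALSE))
  }
  res <- res[order(res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

random_seq <- function(n, p = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p), collapse = "")
}

random_halfsite <- function(len = sample(4:6, 1)) {
  paste(vapply(seq_len(len), function(i) {
    k <- sample(1:4, 1, prob = c(0.55, 0.25, 0.1, 0.1))
    s <- sample(c("A", "C", "G", "T"), k)
    if (k == 1) s else if (k == 4) "N" else paste0("[", paste(s, collapse = ""), "]")
  }, ""), collapse = "")
}

random_element <- function() {
  compile_element(random_halfsite(),
                  geometry = sample(c("IR", "DR", "ER"), 1),
                  spacer = sample(0:3, 1))
}

# hand-built species_hits for conservation tests that need exact layouts
fake_table <- function(species, gene_id = character(0), gene_offset = integer(0),
                       mismatches = 0L, n_genes_total = 10L) {
  n <- length(gene_id)
  hits <- data.frame(species = rep_len(species, n), gene_id = gene_id,
                     seq_id = rep_len("chr1", n), genomic_start0 = rep_len(0L, n),
                     strand = rep_len("+", n),
                     gene_offset = as.integer(gene_offset),
                     mismatches = as.integer(rep_len(mismatches, n)),
                     matched = rep_len("GGGTTAGTGACCC", n), stringsAsFactors = FALSE)
  structure(list(species = species, hits = hits,
                 n_genes_hit = length(unique(hits$gene_id)),
                 n_genes_total = n_genes_total, config = NULL),
            class = "species_hits")
}

# standard 3-species planted bundle used by several test files
planted_bundle <- function(seed = 7L, genes = 3L,
                           offsets = c(800L, 760L, 840L, -1500L, -1480L, -1520L,
                                       5000L, 5010L, 4990L)) {
  cfg <- synthetic_config(n_species = 3, genes_per_species = genes, seed = seed)
  plants <- expand.grid(species = paste0("sp", 1:3),
                        group_id = paste0("grp", seq_len(min(3L, genes))),
                        stringsAsFactors = FALSE)
  plants$offset <- offsets[seq_len(nrow(plants))]
  generate_species_set(cfg, plants)
}

screen_bundle <- function(bundle, max_mm = 0L) {
  lapply(names(bundle$genomes), function(sp)
    run_screen(screen_config(sp, max_mm = max_mm),
               bundle$genomes[[sp]], bundle$anchors[[sp]]))
}
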
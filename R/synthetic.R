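#' Configuration for a synthetic multi-species genome bundle
#'
#' Describes the study conditions emulated by the simulator: a small set of
#' species, each with one contig carrying evenly spaced single-exon genes in
#' alternating orientation over i.i.d. background sequence, linked 1:1 into
#' ortholog groups by gene slot. Defaults give three species (as in the
#' human/mouse/rat screen) with windows wide enough for the full
#' -20,000..+10,000 bp extraction.
#'
#' @param n_species Number of species (default 3).
#' @param genes_per_species Genes (= ortholog groups) per species.
#' @param upstream,downstream Window extents the genes must accommodate.
#' @param gene_length,exon_length Gene span and first-exon length in bp.
#' @param composition Named background base probabilities (A,C,G,T), must
#'   sum to 1 within 1e-9.
#' @param seed Integer RNG seed recorded in the bundle manifest.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_species = 3L, genes_per_species = 5L,
                             upstream = 20000L, downstream = 10000L,
                             gene_length = 1000L, exon_length = 200L,
                             composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                             seed = 1L) {
  stopifnot(n_species >= 1L, genes_per_species >= 1L, upstream > 0L,
            downstream > 0L, gene_length > exon_length, exon_length > 0L)
  composition <- composition[BASES]
  stopifnot(!anyNA(composition), all(composition >= 0),
            abs(sum(composition) - 1) <= 1e-9)
  margin <- max(upstream, downstream) + 500L
  spacing <- upstream + downstream + gene_length + 1000L
  structure(list(
    n_species = as.integer(n_species),
    genes_per_species = as.integer(genes_per_species),
    upstream = as.integer(upstream), downstream = as.integer(downstream),
    gene_length = as.integer(gene_length), exon_length = as.integer(exon_length),
    composition = composition, seed = as.integer(seed),
    margin = margin, spacing = spacing,
    contig_length = margin + (as.integer(genes_per_species) - 1L) * spacing +
      max(upstream, downstream) + gene_length + 500L
  ), class = "synthetic_config")
}

#' Draw a sequence matching a pattern at an exact mismatch count
#'
#' Samples a nucleotide string of the element's full length whose
#' constrained positions deviate from the allowed sets at exactly `n_mm`
#' randomly chosen positions (only positions whose allowed set is a proper
#' subset of \{A,C,G,T\} can be corrupted). Matched constrained positions
#' draw uniformly from their allowed set; spacer positions draw from the
#' background composition.
#'
#' @param element A `response_element`.
#' @param n_mm Exact number of mismatches to introduce.
#' @param composition Background base probabilities for spacer positions.
#' @return A nucleotide string `s` with `mismatches_at(s, 0, element) == n_mm`.
#' @export
sample_element <- function(element, n_mm = 0L,
                           composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(element, "response_element"))
  n_mm <- as.integer(n_mm)
  sets <- element$full$sets
  constrained <- setdiff(seq_along(sets), element$spacer_idx)
  eligible <- constrained[vapply(sets[constrained], length, 1L) < 4L]
  if (n_mm < 0L || n_mm > length(eligible))
    stop("n_mm = ", n_mm, " but only ", length(eligible),
         " constrained position(s) can mismatch")
  corrupt <- if (n_mm > 0L) sample(eligible, n_mm) else integer(0)
  composition <- composition[BASES]
  vapply(seq_along(sets), function(j) {
    if (j %in% element$spacer_idx) {
      sample(BASES, 1L, prob = composition)
    } else if (j %in% corrupt) {
      sample(setdiff(BASES, sets[[j]]), 1L)
    } else {
      s <- sets[[j]]
      if (length(s) == 1L) s else sample(s, 1L)
    }
  }, "") |> paste(collapse = "")
}

#' Analytic expected background hit count
#'
#' Expected number of pattern matches (zero mismatches, single strand) in an
#' i.i.d. background of the given length and base composition: the per-window
#' match probability is the product over positions of the summed allowed-base
#' probabilities (spacer positions contribute 1), times the number of window
#' starts. For a self-reverse-complementary pattern this single-strand value
#' is also the canonical both-strand expectation.
#'
#' @param element A `response_element`.
#' @param length Sequence length in bp (must be >= the pattern length).
#' @param composition Named base probabilities (A,C,G,T).
#' @return Expected hit count (real).
#' @export
#' @examples
#' expected_background_hits(ir1_element(), 30000)  # ~0.0286
expected_background_hits <- function(element, length,
                                     composition = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
  stopifnot(inherits(element, "response_element"))
  L <- element$full$length
  stopifnot(length >= L)
  composition <- composition[BASES]
  p_match <- prod(vapply(element$full$sets, function(s) sum(composition[s]), 1))
  (length - L + 1) * p_match
}

random_background <- function(n, composition) {
  paste(sample(BASES, n, replace = TRUE, prob = composition), collapse = "")
}

# genomic plus-strand interval [start0, end0) of an element of length L
# planted at gene-relative offset k (+1 convention) around anchor a
plant_interval <- function(a, strand, k, L) {
  if (k == 0L) stop("gene-relative offset 0 does not exist (+1 convention)")
  p <- if (k > 0L) k - 1L else k  # oriented distance of 5' base from anchor
  if (strand == "+") c(a + p, a + p + L) else c(a - p - L + 1L, a - p + 1L)
}

#' Generate a synthetic multi-species genome bundle with planted elements
#'
#' Builds, for each species, one contig of i.i.d. background sequence with
#' single-exon genes in alternating orientation, plants the given response
#' element at specified gene-relative offsets (on the gene strand by
#' default), and emits genomes, annotations, the ortholog map and a truth
#' table. Before accepting a species' background, the whole contig is
#' pre-screened for spurious exact matches outside the planted sites and
#' redrawn from the ongoing RNG stream if any are found, so exact planting
#' is recoverable at precision = recall = 1. Deterministic for a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @param plants data.frame with columns `group_id` (e.g. `"grp1"`),
#'   `species` (e.g. `"sp1"`), `offset` (signed gene-relative, +1
#'   convention) and optionally `n_mm` (corruption count, default 0) and
#'   `opposite_strand` (default FALSE).
#' @param element The `response_element` to plant (default [ir1_element()]).
#' @param out_dir Optional directory; when given, writes `<sp>.fasta`,
#'   `<sp>.gff3`, `orthologs.tsv`, `truth.tsv` and `manifest.txt`.
#' @return List with `genomes` (named list of DNAStringSet), `annotations`
#'   (named list of GRanges), `anchors` (named list of data.frames),
#'   `orthologs`, `truth` (data.frames), `config`, and `paths` when
#'   `out_dir` was given.
#' @export
generate_species_set <- function(config, plants = NULL, element = ir1_element(),
                                 out_dir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  L <- element$full$length
  if (is.null(plants))
    plants <- data.frame(group_id = character(0), species = character(0),
                         offset = integer(0))
  if (is.null(plants$n_mm)) plants$n_mm <- rep(0L, nrow(plants))
  if (is.null(plants$opposite_strand)) plants$opposite_strand <- rep(FALSE, nrow(plants))

  species <- paste0("sp", seq_len(config$n_species))
  slots <- seq_len(config$genes_per_species)
  orthologs <- do.call(rbind, lapply(species, function(sp)
    data.frame(group_id = paste0("grp", slots), species = sp,
               gene_id = paste0(sp, "_g", slots), stringsAsFactors = FALSE)))

  anchors_of <- function(sp) {
    strand <- ifelse(slots %% 2L == 1L, "+", "-")
    a <- config$margin + (slots - 1L) * config$spacing
    data.frame(gene_id = paste0(sp, "_g", slots), species = sp, seq_id = "chr1",
               strand = strand, anchor = as.integer(a), stringsAsFactors = FALSE)
  }

  check_plant <- function(k) {
    if (k == 0L) stop("gene-relative offset 0 does not exist (+1 convention)")
    ok_down <- k >= 1L && (k - 1L + L) <= config$downstream
    ok_up <- k <= -1L && k >= -config$upstream
    if (!(ok_down || ok_up))
      stop("infeasible plant offset ", k, " for window -", config$upstream,
           "..+", config$downstream, " and element length ", L)
  }

  genomes <- list(); annotations <- list(); anchors <- list(); truth_rows <- list()
  for (sp in species) {
    anc <- anchors_of(sp)
    anchors[[sp]] <- anc
    pl <- plants[plants$species == sp, , drop = FALSE]
    # resolve gene + genomic interval per plant, check collisions up front
    placed <- lapply(seq_len(nrow(pl)), function(i) {
      g <- orthologs$gene_id[orthologs$species == sp &
                               orthologs$group_id == pl$group_id[i]]
      if (length(g) != 1L) stop("plant group '", pl$group_id[i],
                                "' has no gene in species ", sp)
      row <- anc[anc$gene_id == g, ]
      check_plant(pl$offset[i])
      iv <- plant_interval(row$anchor, row$strand, as.integer(pl$offset[i]), L)
      list(gene_id = g, strand = row$strand, iv = iv, spec = pl[i, ])
    })
    if (length(placed) >= 2L) {
      ivs <- t(vapply(placed, function(p) p$iv, c(0L, 0L)))
      o <- order(ivs[, 1L])
      overlap <- which(ivs[o, 1L][-1L] < ivs[o, 2L][-nrow(ivs)])
      if (length(overlap))
        stop("colliding plants in ", sp, ": ",
             paste(vapply(placed[o][c(overlap, overlap + 1L)],
                          function(p) p$spec$group_id, ""), collapse = ", "))
    }
    planted_starts <- vapply(placed, function(p) p$iv[1L], 0L)

    repeat {  # pre-screen background for spurious exact matches; redraw if any
      contig <- random_background(config$contig_length, config$composition)
      records <- list()
      for (p in placed) {
        elem <- sample_element(element, n_mm = as.integer(p$spec$n_mm),
                               composition = config$composition)
        plus_txt <- if (p$strand == "+") elem else revcomp(elem)
        if (isTRUE(p$spec$opposite_strand)) plus_txt <- revcomp(plus_txt)
        substr(contig, p$iv[1L] + 1L, p$iv[2L]) <- plus_txt
        elem_strand <- if (xor(p$strand == "-", isTRUE(p$spec$opposite_strand))) "-" else "+"
        records[[length(records) + 1L]] <- data.frame(
          species = sp, gene_id = p$gene_id, group_id = p$spec$group_id,
          genomic_start0 = p$iv[1L], gene_offset = as.integer(p$spec$offset),
          strand = elem_strand, planted_seq = elem,
          corruption = as.integer(p$spec$n_mm), stringsAsFactors = FALSE)
      }
      bg_hits <- scan_motif(contig, element, max_mm = 0L, strands = "both")
      spurious <- setdiff(bg_hits$start, planted_starts)
      if (length(spurious) == 0L) break
    }
    genomes[[sp]] <- Biostrings::DNAStringSet(stats::setNames(contig, "chr1"))
    truth_rows[[sp]] <- if (length(records)) do.call(rbind, records) else NULL
    annotations[[sp]] <- anchors_to_granges(anc, config)
  }

  truth <- do.call(rbind, truth_rows)
  if (is.null(truth))
    truth <- data.frame(species = character(0), gene_id = character(0),
                        group_id = character(0), genomic_start0 = integer(0),
                        gene_offset = integer(0), strand = character(0),
                        planted_seq = character(0), corruption = integer(0),
                        stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  rownames(orthologs) <- NULL

  bundle <- list(genomes = genomes, annotations = annotations, anchors = anchors,
                 orthologs = orthologs, truth = truth, config = config)
  if (!is.null(out_dir)) bundle$paths <- write_bundle(bundle, out_dir)
  bundle
}

# single-exon gene models as a GRanges ready for rtracklayer::export
anchors_to_granges <- function(anc, config) {
  gl <- config$gene_length; el <- config$exon_length
  mk <- function(type, s0, e0, id, parent) {
    GenomicRanges::GRanges("chr1", IRanges::IRanges(s0 + 1L, e0), # 0-based half-open in
      strand = "*", type = type, ID = id, Parent = parent)        # -> 1-based inclusive
  }
  rows <- lapply(seq_len(nrow(anc)), function(i) {
    a <- anc$anchor[i]; gid <- anc$gene_id[i]; st <- anc$strand[i]
    if (st == "+") { gs <- a; ge <- a + gl; es <- a; ee <- a + el }
    else { gs <- a - gl + 1L; ge <- a + 1L; es <- a - el + 1L; ee <- a + 1L }
    tid <- paste0(gid, ".t1"); eid <- paste0(gid, ".e1")
    g <- c(mk("gene", gs, ge, gid, NA_character_),
           mk("mRNA", gs, ge, tid, gid),
           mk("exon", es, ee, eid, tid))
    GenomicRanges::strand(g) <- st
    g
  })
  gr <- do.call(c, rows)
  parent <- as.list(gr$Parent)
  parent[is.na(gr$Parent)] <- list(character(0))
  gr$Parent <- IRanges::CharacterList(parent)
  gr
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  for (sp in names(bundle$genomes)) {
    fa <- file.path(out_dir, paste0(sp, ".fasta"))
    gff <- file.path(out_dir, paste0(sp, ".gff3"))
    Biostrings::writeXStringSet(bundle$genomes[[sp]], fa)
    rtracklayer::export(bundle$annotations[[sp]], gff, format = "gff3")
    paths[[sp]] <- c(fasta = fa, gff3 = gff)
  }
  ortho <- file.path(out_dir, "orthologs.tsv")
  utils::write.table(bundle$orthologs, ortho, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- file.path(out_dir, "truth.tsv")
  utils::write.table(bundle$truth, truth, sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- file.path(out_dir, "manifest.txt")
  cfg <- bundle$config
  writeLines(c(
    paste0("seed=", cfg$seed),
    paste0("n_species=", cfg$n_species),
    paste0("genes_per_species=", cfg$genes_per_species),
    paste0("upstream=", cfg$upstream),
    paste0("downstream=", cfg$downstream),
    paste0("contig_length=", cfg$contig_length),
    paste0("composition=", paste(sprintf("%s:%g", names(cfg$composition),
                                         cfg$composition), collapse = ","))
  ), manifest)
  c(paths, list(orthologs = ortho, truth = truth, manifest = manifest))
}
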
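#' Read an ortholog mapping TSV
#'
#' One row per group membership: columns `group_id`, `species`, `gene_id`.
#' A species may appear at most once per group.
#'
#' @param path TSV file with a header line.
#' @return data.frame with the three columns.
#' @export
read_orthologs <- function(path) {
  o <- utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                         colClasses = "character")
  stopifnot(all(c("group_id", "species", "gene_id") %in% names(o)))
  dup <- duplicated(o[, c("group_id", "species")])
  if (any(dup))
    stop("species listed twice in group(s): ",
         paste(unique(o$group_id[dup]), collapse = ", "))
  o
}

#' Intersect per-species hit tables over ortholog groups
#'
#' Implements the cross-species conservation filter: a gene passes when its
#' orthologs carry at least one element in every species (`presence` mode)
#' and, in `positional` mode, additionally when the per-species best hits
#' lie within `tolerance` bp of each other on the gene-relative axis.
#' "Best hit" per species is the fewest-mismatch hit, ties broken 5'-most
#' (smallest gene-relative offset). Genes missing from a species' table,
#' or ortholog gene ids not screened, count as absent.
#'
#' @param tables List of `species_hits` objects (>= 2 species).
#' @param orthologs data.frame as from [read_orthologs()].
#' @param mode `"presence"` (default, least assumptive) or `"positional"`.
#' @param tolerance Maximum pairwise gene-relative offset difference in bp
#'   for positional mode (default 2000).
#' @return data.frame of class `conserved_candidates`, one row per ortholog
#'   group, sorted by `positional_spread` ascending: `group_id`,
#'   `n_species`, `n_species_hit`, `presence_all`, `positional_spread`
#'   (max pairwise |offset difference| among best hits, NA when fewer than
#'   two species have hits), `passes`. The per-species best hits are
#'   attached as attribute `"best_hits"`.
#' @export
conserved_candidates <- function(tables, orthologs, mode = c("presence", "positional"),
                                 tolerance = 2000L) {
  mode <- match.arg(mode)
  stopifnot(length(tables) >= 2L, all(vapply(tables, inherits, TRUE, "species_hits")))
  species <- vapply(tables, function(t) t$species, "")
  if (anyDuplicated(species)) stop("duplicate species among hit tables")
  hits_by_species <- stats::setNames(lapply(tables, function(t) t$hits), species)

  groups <- unique(orthologs$group_id)
  best_rows <- list()
  rows <- lapply(groups, function(g) {
    members <- orthologs[orthologs$group_id == g, , drop = FALSE]
    best <- lapply(seq_len(nrow(members)), function(i) {
      sp <- members$species[i]
      if (!sp %in% species) return(NULL)
      h <- hits_by_species[[sp]]
      h <- h[h$gene_id == members$gene_id[i], , drop = FALSE]
      if (nrow(h) == 0L) return(NULL)
      h <- h[order(h$mismatches, h$gene_offset), , drop = FALSE]
      h[1L, c("species", "gene_id", "gene_offset", "mismatches", "matched")]
    })
    best <- do.call(rbind, best)
    n_hit <- if (is.null(best)) 0L else nrow(best)
    presence_all <- n_hit == nrow(members)
    spread <- if (n_hit >= 2L) diff(range(best$gene_offset)) else NA_real_
    passes <- presence_all &&
      (mode == "presence" || (!is.na(spread) && spread <= tolerance))
    if (!is.null(best)) {
      best$group_id <- g
      best_rows[[g]] <<- best
    }
    data.frame(group_id = g, n_species = nrow(members), n_species_hit = n_hit,
               presence_all = presence_all,
               positional_spread = as.numeric(spread), passes = passes,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    res <- data.frame(group_id = character(0), n_species = integer(0),
                      n_species_hit = integer(0), presence_all = logical(0),
                      positional_spread = numeric(0), passes = logical(0),
                      stringsAsFactors = FALSE)
  res <- res[order(res$positional_spread, res$group_id, na.last = TRUE), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "best_hits") <- do.call(rbind, best_rows)
  attr(res, "mode") <- mode
  attr(res, "tolerance") <- tolerance
  class(res) <- c("conserved_candidates", "data.frame")
  res
}
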
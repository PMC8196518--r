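# Orthogroup classification and duplication statistics for a two-species
# (two-cultivar) membership table.  Orthogroup inference itself (e.g.
# OrthoFinder) is consumed as input, not reimplemented.

#' Read an orthogroup membership table
#'
#' @param path TSV with columns `gene_id`, `species`, `group_id` ("-" for
#'   unassigned genes).
#' @return Validated data frame.
#' @export
read_orthotable <- function(path) {
  validate_orthotable(read_tsv_file(path))
}

validate_orthotable <- function(tab) {
  stopifnot(all(c("gene_id", "species", "group_id") %in% colnames(tab)))
  tab$group_id <- as.character(tab$group_id)
  if (anyDuplicated(tab$gene_id)) stop("gene_id values must be unique")
  sp <- sort(unique(tab$species))
  if (length(sp) != 2L) stop("exactly two species labels required")
  tab
}

# per-group species counts (excluding unassigned genes)
group_counts <- function(tab, species) {
  g <- tab[tab$group_id != "-", , drop = FALSE]
  if (!nrow(g)) {
    return(data.frame(group_id = character(), n_a = integer(), n_b = integer()))
  }
  t1 <- table(factor(g$group_id), factor(g$species, levels = species))
  data.frame(group_id = rownames(t1), n_a = as.integer(t1[, 1L]),
             n_b = as.integer(t1[, 2L]), stringsAsFactors = FALSE)
}

#' Classify orthogroups
#'
#' Per-group class from the two species' gene counts:
#' `A_specific` / `B_specific` (one species only), `single_copy_pair`
#' (1 + 1), `A_single_B_dup` (one A gene, several B genes — the A gene is
#' duplicated in B), `B_single_A_dup`, `multi_multi` (several of both).
#' Unassigned genes (`group_id == "-"`) are species-specific but form no
#' group.
#'
#' @param tab Orthotable (see [read_orthotable()]).
#' @return Data frame: `group_id`, `n_a`, `n_b`, `class`, with attribute
#'   `"species"` giving the (sorted) species labels mapped to A and B.
#' @export
classify_groups <- function(tab) {
  tab <- validate_orthotable(tab)
  sp <- sort(unique(tab$species))
  gc <- group_counts(tab, sp)
  cls <- with(gc, ifelse(n_b == 0L, "A_specific",
               ifelse(n_a == 0L, "B_specific",
               ifelse(n_a == 1L & n_b == 1L, "single_copy_pair",
               ifelse(n_a == 1L & n_b > 1L, "A_single_B_dup",
               ifelse(n_b == 1L & n_a > 1L, "B_single_A_dup", "multi_multi"))))))
  gc$class <- cls
  attr(gc, "species") <- sp
  gc
}

#' Flag gene-duplication events
#'
#' A group holds a duplication event iff one species' gene count strictly
#' exceeds twice the other's, with both counts at least 1.
#'
#' @param tab Orthotable.
#' @return Data frame `group_id`, `n_a`, `n_b`, `duplication_event`.
#' @export
duplication_events <- function(tab) {
  tab <- validate_orthotable(tab)
  sp <- sort(unique(tab$species))
  gc <- group_counts(tab, sp)
  gc$duplication_event <- gc$n_a >= 1L & gc$n_b >= 1L &
    (gc$n_a > 2L * gc$n_b | gc$n_b > 2L * gc$n_a)
  gc
}

#' Duplication summary
#'
#' Tallies single-copy-in-one / duplicated-in-the-other groups in both
#' directions with the per-gene duplication ratio (duplicated genes per
#' single-copy counterpart gene, 2 decimals), species-specific gene counts,
#' and multi-multi groups.
#'
#' @param tab Orthotable.
#' @return Nested list of tallies.
#' @export
duplication_summary <- function(tab) {
  cg <- classify_groups(tab)
  tab <- validate_orthotable(tab)
  sp <- attr(cg, "species")
  n_groups <- function(cl) sum(cg$class == cl)
  genes_in <- function(cl, col) sum(cg[[col]][cg$class == cl])
  ratio <- function(genes, groups) if (groups > 0L) round(genes / groups, 2) else NULL
  unassigned <- table(factor(tab$species[tab$group_id == "-"], levels = sp))
  specific_genes <- vapply(sp, function(s) {
    in_spec_groups <- if (s == sp[1L]) genes_in("A_specific", "n_a")
                      else genes_in("B_specific", "n_b")
    in_spec_groups + as.integer(unassigned[[s]])
  }, numeric(1))
  list(
    species = sp,
    A_single_B_dup = list(
      n_groups = n_groups("A_single_B_dup"),
      total_dup_genes = genes_in("A_single_B_dup", "n_b"),
      ratio = ratio(genes_in("A_single_B_dup", "n_b"), n_groups("A_single_B_dup"))),
    B_single_A_dup = list(
      n_groups = n_groups("B_single_A_dup"),
      total_dup_genes = genes_in("B_single_A_dup", "n_a"),
      ratio = ratio(genes_in("B_single_A_dup", "n_a"), n_groups("B_single_A_dup"))),
    single_copy_pairs = n_groups("single_copy_pair"),
    multi_multi = list(
      n_groups = n_groups("multi_multi"),
      genes_A = genes_in("multi_multi", "n_a"),
      genes_B = genes_in("multi_multi", "n_b")),
    species_specific = list(
      groups_A = n_groups("A_specific"), groups_B = n_groups("B_specific"),
      genes_A = specific_genes[[1L]], genes_B = specific_genes[[2L]])
  )
}
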
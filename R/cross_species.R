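# Cross-species ortholog mapping and DEG intersection ----------------------

# Validate an ortholog map against its structural invariants.
.validate_ortholog_map <- function(map) {
  need <- c("human_gene", "mouse_gene", "relationship", "primary")
  if (!all(need %in% names(map))) {
    stop("ortholog map must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  if (!all(map$relationship %in% c("one2one", "one2many", "many2one"))) {
    stop("ortholog map has unknown relationship value(s)", call. = FALSE)
  }
  o2o <- map[map$relationship == "one2one", ]
  if (anyDuplicated(o2o$human_gene) || anyDuplicated(o2o$mouse_gene)) {
    stop("one2one rows must be unique both ways", call. = FALSE)
  }
  o2m <- map[map$relationship == "one2many", ]
  if (nrow(o2m)) {
    nprim <- tapply(o2m$primary, o2m$human_gene, sum)
    if (any(nprim != 1L)) {
      stop("each one2many human gene must have exactly one primary target",
           call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Map human genes to mouse gene space
#'
#' One-to-one orthologs map directly; one-to-many human genes map to their
#' primary-flagged target only; many-to-one human genes each map to the
#' shared target (duplicates collapse in the returned set); genes absent
#' from the map are excluded and counted.
#'
#' @param human_genes character vector of human gene symbols.
#' @param map ortholog map data.frame (`human_gene`, `mouse_gene`,
#'   `relationship`, `primary`).
#' @return list with `mapped` (unique mouse gene set), `report` (named
#'   counts: input, mapped, excluded), and `excluded` (the unmapped
#'   symbols).
#' @export
map_orthologs <- function(human_genes, map) {
  .validate_ortholog_map(map)
  human_genes <- unique(human_genes)
  use <- map[map$primary & map$human_gene %in% human_genes, , drop = FALSE]
  mapped_from <- unique(use$human_gene)
  excluded <- setdiff(human_genes, map$human_gene)
  # genes present in the map only through non-primary rows map nowhere
  silent <- setdiff(setdiff(human_genes, mapped_from), excluded)
  excluded <- c(excluded, silent)
  list(mapped = unique(use$mouse_gene),
       report = c(n_input = length(human_genes),
                  n_mapped = length(mapped_from),
                  n_excluded = length(excluded)),
       excluded = excluded)
}

#' Cross-species DEG intersection per broad cell class
#'
#' Maps each class's human DEGs into mouse gene space through the ortholog
#' map and intersects them with the mouse DEGs of the matching class
#' (case-insensitively, since symbol casing conventions differ between the
#' species). Also returns the exclusive (UpSet) counts over the two mapped
#' sets per class.
#'
#' @param human_degs named list: class -> human significant gene set.
#' @param mouse_degs named list: class -> mouse significant gene set.
#' @param map ortholog map data.frame.
#' @return list keyed by class, each with `intersection` (mouse-space gene
#'   set), `n_human_mapped`, `n_mouse`, `upset` (exclusive counts), and
#'   `mapping_report`.
#' @export
intersect_cross_species <- function(human_degs, mouse_degs, map) {
  if (!setequal(names(human_degs), names(mouse_degs))) {
    stop("class mismatch between the two species' DEG lists",
         call. = FALSE)
  }
  out <- lapply(names(human_degs), function(cl) {
    mp <- map_orthologs(human_degs[[cl]], map)
    hm <- toupper(mp$mapped)
    ms <- toupper(unique(mouse_degs[[cl]]))
    inter_idx <- ms %in% hm
    inter <- unique(mouse_degs[[cl]])[inter_idx]
    list(intersection = inter,
         n_human_mapped = length(hm),
         n_mouse = length(ms),
         upset = upset_exclusive_counts(list(human = hm, mouse = ms)),
         mapping_report = mp$report)
  })
  stats::setNames(out, names(human_degs))
}
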
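# Bundled gene lists.
#
# The circadian gene classes (13 clock-control + 35 core-clock = 48 genes)
# and the 60 immune-checkpoint genes ship as curated synthetic
# reconstructions: membership was assembled from the circadian and
# immuno-oncology literature to match the published class sizes, not
# copied from any single supplementary table, hence the `synthetic`
# label in the file names.  Users with their own lists supply a GMT.

#' Bundled circadian rhythm gene sets
#'
#' Returns the packaged clock-control (13 genes) and core-clock (35 genes)
#' sets as a `gene_set_pair`. The list is a curated synthetic
#' reconstruction (see file `crg_sets_synthetic.gmt`).
#'
#' @return a [gene_set_pair()] with elements `control` and `core`.
#' @export
crg_gene_sets <- function() {
  path <- system.file("extdata", "crg_sets_synthetic.gmt", package = "crscore")
  gmt <- read_gmt(path)
  gene_set_pair(control = gmt[["clock_control"]], core = gmt[["core_clock"]])
}

#' Bundled immune checkpoint gene list
#'
#' 60 immune checkpoint genes (ligands, receptors and pathway members such
#' as PDCD1/PD-1, CD274/PD-L1, CTLA4, CD276) as a one-set collection.
#' Curated synthetic reconstruction (see `icg_synthetic.gmt`).
#'
#' @return a `gene_set_collection` with one set, `immune_checkpoint`.
#' @export
icg_gene_sets <- function() {
  read_gmt(system.file("extdata", "icg_synthetic.gmt", package = "crscore"))
}

#' Bundled placeholder stromal/immune signatures
#'
#' Synthetic placeholder signatures for the stromal/immune signature
#' scores; real ESTIMATE signatures can be supplied as a GMT with sets
#' named `stromal_signature` and `immune_signature`.
#'
#' @return a `gene_set_collection` with sets `stromal_signature` and
#'   `immune_signature`.
#' @export
estimate_gene_sets <- function() {
  read_gmt(system.file("extdata", "estimate_signatures_synthetic.gmt",
                       package = "crscore"))
}

#' Construct a clock-control / core-clock gene-set pair
#'
#' The two classes whose per-sample enrichment difference defines the CRS.
#' Sets must be disjoint and non-empty.
#'
#' @param control character vector of clock-control gene ids.
#' @param core character vector of core-clock gene ids.
#' @return list of class `gene_set_pair` with elements `control`, `core`.
#' @export
gene_set_pair <- function(control, core) {
  control <- unique(trimws(control))
  core <- unique(trimws(core))
  if (length(control) == 0L || length(core) == 0L)
    stop("both gene sets must be non-empty")
  overlap <- intersect(control, core)
  if (length(overlap))
    stop("control and core sets must be disjoint; shared: ",
         paste(overlap, collapse = ", "))
  structure(list(control = control, core = core), class = "gene_set_pair")
}
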
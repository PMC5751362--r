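#' Map one SNP to genes by containment or nearest gene within a flank
#'
#' A SNP located inside one or more gene intervals (1-based inclusive, same
#' chromosome) maps to ALL containing genes with relation `inside` and
#' distance 0.  Otherwise it maps to the single nearest gene whose nearer
#' interval endpoint lies within `flank_bp` base pairs (ties broken by
#' lexicographically smallest gene id), with relation `flank_upstream` when
#' the SNP precedes the gene start and `flank_downstream` when it follows
#' the gene end.  SNPs farther than `flank_bp` from every gene map to
#' nothing.  Distances are strand-agnostic.
#'
#' @param snp a list or one-row data frame with `snp_id`, `chromosome`,
#'   `position`.
#' @param annotation gene annotation data frame from [read_gene_bed()] (or
#'   [simulate_gene_annotation()]).
#' @param flank_bp flanking window in base pairs (default 5000).
#' @return data frame with columns `snp_id`, `gene_id`, `relation`,
#'   `distance` (possibly zero rows).
#' @export
map_snp <- function(snp, annotation, flank_bp = 5000) {
  empty <- data.frame(snp_id = character(), gene_id = character(),
                      relation = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  ann <- annotation[annotation$chromosome == snp$chromosome, , drop = FALSE]
  if (nrow(ann) == 0L) return(empty)
  pos <- as.integer(snp$position)
  inside <- ann$start <= pos & pos <= ann$end
  if (any(inside)) {
    g <- sort(ann$gene_id[inside])
    return(data.frame(snp_id = rep(snp$snp_id, length(g)), gene_id = g,
                      relation = "inside", distance = 0L,
                      stringsAsFactors = FALSE))
  }
  d <- pmin(abs(pos - ann$start), abs(pos - ann$end))
  ok <- d <= flank_bp & d > 0
  if (!any(ok)) return(empty)
  dmin <- min(d[ok])
  cand <- ann[ok & d == dmin, , drop = FALSE]
  cand <- cand[order(cand$gene_id), , drop = FALSE][1L, ]
  relation <- if (pos < cand$start) "flank_upstream" else "flank_downstream"
  data.frame(snp_id = snp$snp_id, gene_id = cand$gene_id,
             relation = relation, distance = as.integer(dmin),
             stringsAsFactors = FALSE)
}

#' Map many SNPs to genes
#'
#' @param snps data frame with `snp_id`, `chromosome`, `position` (e.g. the
#'   output of [screen_risk_snps()]).
#' @inheritParams map_snp
#' @return data frame concatenating [map_snp()] results for all SNPs.
#' @export
map_snps <- function(snps, annotation, flank_bp = 5000) {
  if (nrow(snps) == 0L) {
    return(data.frame(snp_id = character(), gene_id = character(),
                      relation = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  }
  rows <- lapply(seq_len(nrow(snps)), function(i)
    map_snp(snps[i, ], annotation, flank_bp))
  do.call(rbind, rows)
}

#' Collapse SNP-to-gene mappings into a unique risk-gene set
#'
#' @param mappings data frame from [map_snps()].
#' @return list with `gene_ids` (unique, lexicographically sorted) and
#'   `provenance` (named list mapping each gene to its supporting SNP ids).
#' @export
collapse_genes <- function(mappings) {
  if (nrow(mappings) == 0L) {
    return(list(gene_ids = character(0), provenance = list()))
  }
  genes <- sort(unique(mappings$gene_id))
  prov <- lapply(genes, function(g)
    sort(unique(mappings$snp_id[mappings$gene_id == g])))
  names(prov) <- genes
  list(gene_ids = genes, provenance = prov)
}
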
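# Shared allele-orientation rule: the alt allele is the MINOR allele computed
# over ALL non-missing calls (cases + controls pooled).  Ties are broken by
# taking the lexicographically larger allele as alt; a monomorphic SNP keeps
# its observed allele as ref and gets the placeholder "N" as alt.
.orient_minor <- function(calls, ref, alt) {
  nonmiss <- sum(!is.na(calls))
  n_alt <- sum(calls, na.rm = TRUE)
  n_ref <- 2L * nonmiss - n_alt
  if (n_alt == 0L && n_ref == 0L) {
    return(list(calls = calls, ref = ref, alt = "N"))
  }
  flip <- FALSE
  if (n_alt > n_ref) {
    flip <- TRUE
  } else if (n_alt == n_ref && alt < ref) {
    flip <- TRUE
  }
  if (flip) {
    calls <- 2L - calls
    tmp <- ref; ref <- alt; alt <- tmp
    n_tmp <- n_ref; n_ref <- n_alt; n_alt <- n_tmp
  }
  if (n_alt == 0L) alt <- "N"
  if (n_ref == 0L) ref <- "N"
  list(calls = calls, ref = ref, alt = alt)
}

.new_genotype_dataset <- function(samples, snps, calls) {
  stopifnot(nrow(calls) == nrow(samples), ncol(calls) == nrow(snps))
  rownames(calls) <- samples$sample_id
  colnames(calls) <- snps$snp_id
  structure(list(samples = samples, snps = snps, calls = calls),
            class = "genotype_dataset")
}

#' Read genotypes from PLINK text PED/MAP files
#'
#' Parses the PLINK text dialect: the MAP file has four whitespace-delimited
#' columns (chromosome, SNP id, genetic distance, base-pair position); the PED
#' file has six leading columns (family, individual, father, mother, sex,
#' phenotype) followed by two allele columns per SNP.  Phenotype 1 codes a
#' control, 2 a case; 0 or -9 drops the sample (with a message).  An allele
#' coded "0" marks a missing call.  After parsing, each SNP is oriented so
#' that the minor allele (over all non-missing calls, cases and controls
#' pooled) is the alt allele; genotype codes count alt alleles (0 =
#' reference homozygote, 1 = heterozygote, 2 = alternate homozygote, NA =
#' missing).
#'
#' @param ped_path path to the PED file.
#' @param map_path path to the MAP file.
#' @return A `genotype_dataset`: a list with `samples` (data frame of
#'   `sample_id`, `phenotype`), `snps` (data frame of `snp_id`,
#'   `chromosome`, `position`, `allele_ref`, `allele_alt`) and `calls`
#'   (samples x SNPs integer matrix with NA for missing).
#' @examples
#' dir <- tempfile(); dir.create(dir)
#' writeLines(c("1 rs1 0 100", "1 rs2 0 200"), file.path(dir, "ex.map"))
#' writeLines(c("F1 S1 0 0 1 2 A A G G", "F2 S2 0 0 2 1 A G G G"),
#'            file.path(dir, "ex.ped"))
#' ds <- read_ped_map(file.path(dir, "ex.ped"), file.path(dir, "ex.map"))
#' dim(ds$calls)
#' @export
read_ped_map <- function(ped_path, map_path) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map_fields <- strsplit(trimws(map_lines), "[ \t]+")
  bad <- which(lengths(map_fields) != 4L)
  if (length(bad)) {
    stop(sprintf("MAP format error at line %d: expected 4 columns, found %d",
                 bad[1], length(map_fields[[bad[1]]])))
  }
  snps <- data.frame(
    snp_id = vapply(map_fields, `[`, "", 2L),
    chromosome = vapply(map_fields, `[`, "", 1L),
    position = as.integer(vapply(map_fields, `[`, "", 4L)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(snps$position)) || any(snps$position < 1L)) {
    stop("MAP format error: positions must be integers >= 1")
  }
  n_snps <- nrow(snps)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  ped_fields <- strsplit(trimws(ped_lines), "[ \t]+")
  expected <- 6L + 2L * n_snps
  bad <- which(lengths(ped_fields) != expected)
  if (length(bad)) {
    stop(sprintf("PED format error at line %d: expected %d columns, found %d",
                 bad[1], expected, length(ped_fields[[bad[1]]])))
  }
  sample_id <- vapply(ped_fields, `[`, "", 2L)
  pheno_code <- vapply(ped_fields, `[`, "", 6L)
  unknown <- !pheno_code %in% c("0", "-9", "1", "2")
  if (any(unknown)) {
    stop("PED format error: phenotype codes outside {0, -9, 1, 2} for samples: ",
         paste(sample_id[unknown], collapse = ", "))
  }
  keep <- pheno_code %in% c("1", "2")
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message(sprintf("read_ped_map: dropped %d sample(s) with missing phenotype",
                    n_dropped))
  }
  ped_fields <- ped_fields[keep]
  sample_id <- sample_id[keep]
  pheno <- ifelse(pheno_code[keep] == "2", "case", "control")
  n_samples <- length(ped_fields)

  allele_mat <- matrix("", nrow = n_samples, ncol = 2L * n_snps)
  for (i in seq_len(n_samples)) {
    allele_mat[i, ] <- ped_fields[[i]][-(1:6)]
  }
  calls <- matrix(NA_integer_, nrow = n_samples, ncol = n_snps)
  ref <- character(n_snps); alt <- character(n_snps)
  for (j in seq_len(n_snps)) {
    a1 <- allele_mat[, 2L * j - 1L]
    a2 <- allele_mat[, 2L * j]
    miss <- a1 == "0" | a2 == "0"
    obs <- unique(c(a1[!miss], a2[!miss]))
    if (length(obs) > 2L) {
      stop(sprintf("PED format error: SNP %s has >2 distinct alleles (%s)",
                   snps$snp_id[j], paste(sort(obs), collapse = ",")))
    }
    if (length(obs) == 0L) {
      ref[j] <- "N"; alt[j] <- "N"
      next
    }
    r <- sort(obs)[1L]
    a <- if (length(obs) == 2L) sort(obs)[2L] else "N"
    code <- (a1 == a) + (a2 == a)
    code[miss] <- NA_integer_
    o <- .orient_minor(as.integer(code), r, a)
    calls[, j] <- o$calls
    ref[j] <- o$ref
    alt[j] <- o$alt
  }
  snps$allele_ref <- ref
  snps$allele_alt <- alt
  samples <- data.frame(sample_id = sample_id, phenotype = pheno,
                        stringsAsFactors = FALSE)
  .new_genotype_dataset(samples, snps, calls)
}

#' Read gene intervals from BED3+1 text
#'
#' Expects four tab/whitespace-separated columns: chromosome, start (0-based),
#' end (half-open), gene id.  Coordinates are converted to the package's
#' internal 1-based inclusive convention (`start + 1`, `end`).
#'
#' @param path path to the BED file.
#' @return data frame with columns `gene_id`, `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_gene_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(gene_id = character(), chromosome = character(),
                      start = integer(), end = integer(),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 4L)
  if (length(bad)) {
    stop(sprintf("BED format error at line %d: expected >= 4 columns", bad[1]))
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start0 <- as.integer(vapply(fields, `[`, "", 2L))
  end0 <- as.integer(vapply(fields, `[`, "", 3L))
  gene_id <- vapply(fields, `[`, "", 4L)
  if (any(is.na(start0)) || any(is.na(end0))) {
    stop("BED format error: non-integer coordinates")
  }
  bad <- which(start0 >= end0)
  if (length(bad)) {
    stop(sprintf("BED format error at line %d: start >= end", bad[1]))
  }
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup)) {
    stop("BED format error: duplicated gene_id: ",
         paste(unique(dup), collapse = ", "))
  }
  data.frame(gene_id = gene_id, chromosome = chrom,
             start = start0 + 1L, end = end0, stringsAsFactors = FALSE)
}

#' Read a protein-protein interaction edge list
#'
#' Accepts two or three whitespace/tab-delimited columns: node A, node B and
#' an optional confidence score in \[0, 1\].  When a score column is present,
#' rows with score below `min_score` are dropped.  No deduplication or
#' self-loop removal happens here; that is [build_graph()]'s contract.
#'
#' @param path path to the edge list file.
#' @param min_score minimum confidence score to keep (default 0, keep all).
#' @return data frame with columns `node_a`, `node_b`, `score` (NA when the
#'   file has no score column).
#' @export
read_edge_list <- function(path, min_score = 0) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(node_a = character(), node_b = character(),
                      score = numeric(), stringsAsFactors = FALSE)
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    stop(sprintf("edge list format error at line %d: expected >= 2 columns",
                 bad[1]))
  }
  node_a <- vapply(fields, `[`, "", 1L)
  node_b <- vapply(fields, `[`, "", 2L)
  has_score <- lengths(fields) >= 3L
  score <- rep(NA_real_, length(fields))
  score[has_score] <- as.numeric(vapply(fields[has_score], `[`, "", 3L))
  keep <- is.na(score) | score >= min_score
  data.frame(node_a = node_a[keep], node_b = node_b[keep],
             score = score[keep], stringsAsFactors = FALSE)
}

#' Read gene sets from a GMT file
#'
#' Each line carries a term id, a description and at least one member gene,
#' tab-delimited.  Members are deduplicated within a term.
#'
#' @param path path to the GMT file.
#' @return named list; each element is `list(description =, members =)`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop(sprintf("GMT format error at line %d: expected >= 3 tab-separated fields",
                 bad[1]))
  }
  out <- lapply(fields, function(f) {
    list(description = f[2L], members = unique(f[-(1:2)]))
  })
  names(out) <- vapply(fields, `[`, "", 1L)
  out
}

.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.6g", v)
  }, "")
  out
}

.write_tsv <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  for (j in which(num)) df[[j]] <- .fmt_num(df[[j]])
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  path
}

#' Write pipeline result tables
#'
#' Writes whichever components are present in `results` with deterministic
#' column order and number formatting (six significant digits), so repeated
#' runs on the same inputs produce byte-identical files.  Recognized
#' components: `assoc` (association table; columns CHR, SNP, BP, A1, A2,
#' MAF, MISS, HWE_P, CHISQ, P, OR), `snp_gene` (SNP-to-gene mapping),
#' `genes` (risk gene list), `node_metrics`, `hubs`, `clusters` (columns
#' cluster, score, nodes, edges, member_ids, core_hub), `enrichment`, and
#' `summary` (run-level list, written as JSON).
#'
#' @param results named list of stage outputs.
#' @param out_dir output directory (created if missing).
#' @return character vector of written file paths, invisibly.
#' @export
write_tables <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  if (!is.null(results$assoc)) {
    df <- results$assoc
    out <- data.frame(CHR = df$chromosome, SNP = df$snp_id, BP = df$position,
                      A1 = df$allele_alt, A2 = df$allele_ref,
                      MAF = df$maf, MISS = df$missingness,
                      HWE_P = df$hwe_p, CHISQ = df$chi2, P = df$p,
                      OR = df$odds_ratio, stringsAsFactors = FALSE)
    paths <- c(paths, .write_tsv(out, file.path(out_dir, "assoc.tsv")))
  }
  if (!is.null(results$snp_gene)) {
    paths <- c(paths, .write_tsv(results$snp_gene,
                                 file.path(out_dir, "snp_gene.tsv")))
  }
  if (!is.null(results$genes)) {
    paths <- c(paths, .write_tsv(data.frame(gene_id = results$genes,
                                            stringsAsFactors = FALSE),
                                 file.path(out_dir, "risk_genes.tsv")))
  }
  if (!is.null(results$node_metrics)) {
    paths <- c(paths, .write_tsv(results$node_metrics,
                                 file.path(out_dir, "node_metrics.tsv")))
  }
  if (!is.null(results$hubs)) {
    paths <- c(paths, .write_tsv(results$hubs, file.path(out_dir, "hubs.tsv")))
  }
  if (!is.null(results$clusters)) {
    cl <- results$clusters
    df <- data.frame(
      cluster = seq_along(cl),
      score = vapply(cl, function(x) x$score, 0),
      nodes = vapply(cl, function(x) x$n_nodes, 0L),
      edges = vapply(cl, function(x) x$n_edges, 0L),
      member_ids = vapply(cl, function(x) paste(sort(x$members), collapse = ","), ""),
      core_hub = vapply(cl, function(x)
        if (is.null(x$core_hub) || is.na(x$core_hub)) "" else x$core_hub, ""),
      stringsAsFactors = FALSE
    )
    if (nrow(df) == 0L) {
      df <- data.frame(cluster = integer(), score = numeric(),
                       nodes = integer(), edges = integer(),
                       member_ids = character(), core_hub = character(),
                       stringsAsFactors = FALSE)
    }
    paths <- c(paths, .write_tsv(df, file.path(out_dir, "clusters.tsv")))
  }
  if (!is.null(results$enrichment)) {
    paths <- c(paths, .write_tsv(results$enrichment,
                                 file.path(out_dir, "enrichment.tsv")))
  }
  if (!is.null(results$summary)) {
    p <- file.path(out_dir, "summary.json")
    jsonlite::write_json(results$summary, p, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}
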
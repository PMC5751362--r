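# Seeded synthetic-data generators.  Every generator is a pure function of
# the spec (including its master seed); per-generator substreams are derived
# from the master seed so each input can be regenerated independently.
#
# Two planted-module styles are supported.  "random" rewires the edges inside
# the member set to a requested density, leaving background degrees intact.
# "hub_spoke" is a structured module: one apex node adjacent to every spoke,
# the spokes forming a circulant ring C_m(1, 3); with m = size - 1 in
# [19, 23] the apex's MCODE vertex weight ((d+1)(d+2)/(m+1) with d = 4) is
# strictly maximal and every spoke's weight (1.2) clears the default MCODE
# expansion threshold, so module recovery and core-hub designation are
# deterministic.  A perfect clique, by contrast, ties all member weights, so
# a clique module can never designate a core hub under the strict-maximum
# rule — the two defaults exercise both outcomes.

.substream <- function(seed, idx) {
  (as.integer(seed) %% 65011L) * 32003L + idx * 7919L
}

#' Simulation specification
#'
#' Describes a full synthetic study: case/control genotypes with planted
#' allele-frequency differences of a given odds ratio under Hardy-Weinberg
#' proportions within each group, a tiled gene map with SNPs placed inside
#' genes, within the 5 kb flank, or beyond it, a scale-free
#' (preferential-attachment) protein-interaction background with planted
#' dense modules over the causal genes, and annotation gene sets with a
#' constructed enriched term.
#'
#' @param seed master integer seed.
#' @param n_cases,n_controls sample sizes.
#' @param n_snps number of SNPs.
#' @param maf_range uniform range for control minor-allele frequencies.
#' @param n_causal number of causal SNPs (each in a distinct gene).
#' @param causal_or planted allelic odds ratio for causal SNPs.
#' @param causal_maf control allele frequency at causal SNPs.
#' @param missing_rate independent per-call missingness probability.
#' @param n_genes number of genes tiled over the chromosomes.
#' @param gene_length_bp,intergenic_gap_bp gene tiling geometry; the gap
#'   must exceed 2 * 5000 + 2 so the "beyond 5 kb" stratum exists.
#' @param n_chromosomes number of chromosomes.
#' @param ppi_background_nodes nodes in the interaction background.
#' @param attachment_edges edges added per node by preferential attachment.
#' @param planted_modules list of planted modules.  Each entry is either
#'   `list(size =, density =)` — a random module rewired to the requested
#'   internal density (1 plants a clique) — or
#'   `list(size =, style = "hub_spoke")` — a structured module (apex plus
#'   circulant ring of spokes, size between 20 and 24) whose apex is the
#'   unique maximum-weight member and hence the designated core hub.
#' @return validated list with class `sim_spec`.
#' @export
sim_spec <- function(seed = 1L, n_cases = 1000L, n_controls = 1000L,
                     n_snps = 5000L, maf_range = c(0.05, 0.5),
                     n_causal = 50L, causal_or = 2, causal_maf = 0.3,
                     missing_rate = 0.01, n_genes = 600L,
                     gene_length_bp = 20000L, intergenic_gap_bp = 12000L,
                     n_chromosomes = 4L, ppi_background_nodes = 300L,
                     attachment_edges = 2L,
                     planted_modules = list(
                       list(size = 8L, density = 1.0),
                       list(size = 21L, style = "hub_spoke"))) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_snps >= 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] < 1,
            maf_range[1] <= maf_range[2],
            n_causal >= 0, n_causal <= n_snps, causal_or > 0,
            causal_maf > 0, causal_maf < 1,
            missing_rate >= 0, missing_rate <= 1,
            n_genes >= 1, gene_length_bp >= 1,
            n_chromosomes >= 1, ppi_background_nodes >= 1,
            attachment_edges >= 1)
  if (intergenic_gap_bp <= 2L * 5000L + 2L) {
    stop("intergenic_gap_bp must exceed 10002 so SNPs beyond the 5 kb flank exist")
  }
  for (m in planted_modules) {
    style <- m$style
    if (is.null(style)) style <- "random"
    if (!style %in% c("random", "hub_spoke")) {
      stop("unknown planted module style: ", style)
    }
    if (style == "hub_spoke") {
      if (m$size < 20L || m$size > 24L) {
        stop("hub_spoke module size must be between 20 and 24")
      }
    } else {
      if (m$size < 3L) stop("planted module size must be >= 3")
      if (is.null(m$density) || m$density < 0 || m$density > 1) {
        stop("module density must be in [0, 1]")
      }
    }
    if (m$size > ppi_background_nodes) {
      stop("planted module size exceeds the interaction network node count")
    }
  }
  structure(list(seed = as.integer(seed), n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_snps = as.integer(n_snps), maf_range = maf_range,
                 n_causal = as.integer(n_causal), causal_or = causal_or,
                 causal_maf = causal_maf, missing_rate = missing_rate,
                 n_genes = as.integer(n_genes),
                 gene_length_bp = as.integer(gene_length_bp),
                 intergenic_gap_bp = as.integer(intergenic_gap_bp),
                 n_chromosomes = as.integer(n_chromosomes),
                 ppi_background_nodes = as.integer(ppi_background_nodes),
                 attachment_edges = as.integer(attachment_edges),
                 planted_modules = planted_modules),
            class = "sim_spec")
}

# Deterministic study layout shared by all generators: gene tiling, SNP
# placement strata, causal SNP choice, planted module membership.
.sim_layout <- function(spec) {
  n_per <- ceiling(spec$n_genes / spec$n_chromosomes)
  idx <- seq_len(spec$n_genes) - 1L
  chrom_i <- idx %/% n_per + 1L
  slot <- idx %% n_per
  gap <- spec$intergenic_gap_bp
  len <- spec$gene_length_bp
  start <- gap + slot * (len + gap) + 1L
  annotation <- data.frame(
    gene_id = sprintf("G%04d", idx + 1L),
    chromosome = as.character(chrom_i),
    start = start, end = start + len - 1L,
    stringsAsFactors = FALSE
  )
  set.seed(.substream(spec$seed, 1L))
  stratum <- sample(c("inside", "flank", "far"), spec$n_snps,
                    replace = TRUE, prob = c(0.6, 0.2, 0.2))
  gene_i <- sample.int(spec$n_genes, spec$n_snps, replace = TRUE)
  gs <- annotation$start[gene_i]
  ge <- annotation$end[gene_i]
  pos <- integer(spec$n_snps)
  is_in <- stratum == "inside"
  pos[is_in] <- gs[is_in] +
    floor(stats::runif(sum(is_in)) * (ge[is_in] - gs[is_in] + 1L))
  is_fl <- stratum == "flank"
  d_fl <- 1L + floor(stats::runif(sum(is_fl)) * 5000L)
  upstream <- stats::runif(sum(is_fl)) < 0.5
  pos[is_fl] <- ifelse(upstream, gs[is_fl] - d_fl, ge[is_fl] + d_fl)
  is_far <- stratum == "far"
  d_far <- 5001L + floor(stats::runif(sum(is_far)) * (gap - 10001L))
  pos[is_far] <- ge[is_far] + d_far
  pos <- as.integer(pos)
  d_fl <- as.integer(d_fl)
  truth_distance <- rep(NA_integer_, spec$n_snps)
  truth_distance[is_in] <- 0L
  truth_distance[is_fl] <- d_fl
  snp_map <- data.frame(
    snp_id = sprintf("rs%05d", seq_len(spec$n_snps)),
    chromosome = annotation$chromosome[gene_i],
    position = pos,
    stratum = stratum,
    truth_gene = ifelse(stratum == "far", NA_character_,
                        annotation$gene_id[gene_i]),
    truth_distance = truth_distance,
    stringsAsFactors = FALSE
  )
  # causal SNPs: inside-gene SNPs in distinct genes
  inside_idx <- sample(which(is_in))
  inside_idx <- inside_idx[!duplicated(gene_i[inside_idx])]
  if (length(inside_idx) < spec$n_causal) {
    stop("not enough within-gene SNPs in distinct genes to plant ",
         spec$n_causal, " causal SNPs")
  }
  causal_idx <- sort(inside_idx[seq_len(spec$n_causal)])
  causal_genes <- annotation$gene_id[gene_i[causal_idx]]
  # planted modules claim consecutive chunks of causal genes, topped up
  # from the remaining gene universe when fewer causal genes exist
  modules <- list()
  pool <- causal_genes
  spare <- setdiff(annotation$gene_id, causal_genes)
  for (mi in seq_along(spec$planted_modules)) {
    pm <- spec$planted_modules[[mi]]
    s <- pm$size
    take <- pool[seq_len(min(s, length(pool)))]
    pool <- setdiff(pool, take)
    if (length(take) < s) {
      extra <- spare[seq_len(s - length(take))]
      spare <- setdiff(spare, extra)
      take <- c(take, extra)
    }
    style <- if (is.null(pm$style)) "random" else pm$style
    modules[[mi]] <- list(members = sort(take), style = style,
                          density = pm$density,
                          apex = if (style == "hub_spoke") take[1L] else NULL)
  }
  list(annotation = annotation, snp_map = snp_map,
       causal_idx = causal_idx, causal_genes = causal_genes,
       modules = modules)
}

#' Simulate gene annotation and SNP placement
#'
#' Tiles non-overlapping genes of fixed length across the chromosomes,
#' separated by a fixed intergenic gap, and places SNPs in three recorded
#' strata: inside a gene, within 5 kb of a gene, and farther than 5 kb from
#' every gene.
#'
#' @param spec a [sim_spec()].
#' @return list with `annotation` (gene data frame as [read_gene_bed()]
#'   returns) and `snp_map` (data frame `snp_id`, `chromosome`, `position`,
#'   `stratum`, `truth_gene`, `truth_distance`).
#' @export
simulate_gene_annotation <- function(spec) {
  layout <- .sim_layout(spec)
  list(annotation = layout$annotation, snp_map = layout$snp_map)
}

#' Simulate case/control genotypes with planted effects
#'
#' Control genotypes are drawn from Hardy-Weinberg proportions at a per-SNP
#' allele frequency sampled uniformly from `maf_range`.  Causal SNPs use
#' `causal_maf` in controls and, in cases, the frequency whose allele odds
#' equal `causal_or` times the control odds (again HWE within the group).
#' Non-causal SNPs have identical frequencies in both groups.  Each call is
#' independently masked missing with probability `missing_rate`.  The
#' returned dataset is oriented like [read_ped_map()] output (pooled minor
#' allele = alt), so writing and re-reading it reproduces it exactly.
#'
#' @param spec a [sim_spec()].
#' @return list with `dataset` (a `genotype_dataset`) and `truth` (list with
#'   `causal` data frame: `snp_id`, `gene_id`, `odds_ratio`, `f_control`,
#'   `f_case`).
#' @export
simulate_genotypes <- function(spec) {
  layout <- .sim_layout(spec)
  n_snps <- spec$n_snps
  set.seed(.substream(spec$seed, 2L))
  f_ctrl <- stats::runif(n_snps, spec$maf_range[1], spec$maf_range[2])
  f_ctrl[layout$causal_idx] <- spec$causal_maf
  odds <- f_ctrl / (1 - f_ctrl)
  f_case <- f_ctrl
  co <- odds[layout$causal_idx] * spec$causal_or
  f_case[layout$causal_idx] <- co / (1 + co)
  if (any(f_case >= 1)) {
    stop("infeasible case allele frequency (>= 1) at SNP ",
         layout$snp_map$snp_id[which(f_case >= 1)[1]])
  }
  pairs <- matrix(c("A", "G", "C", "T", "A", "C", "G", "T"), ncol = 2,
                  byrow = TRUE)
  pick <- sample.int(nrow(pairs), n_snps, replace = TRUE)
  ref <- pairs[pick, 1]; alt <- pairs[pick, 2]
  nca <- spec$n_cases; nco <- spec$n_controls
  case_calls <- matrix(stats::rbinom(nca * n_snps, 2L, rep(f_case, each = nca)),
                       nrow = nca)
  ctrl_calls <- matrix(stats::rbinom(nco * n_snps, 2L, rep(f_ctrl, each = nco)),
                       nrow = nco)
  calls <- rbind(case_calls, ctrl_calls)
  if (spec$missing_rate > 0) {
    calls[stats::runif(length(calls)) < spec$missing_rate] <- NA_integer_
  }
  # orient to the reader's convention: pooled minor allele is alt
  nonmiss <- colSums(!is.na(calls))
  n_alt <- colSums(calls, na.rm = TRUE)
  n_ref <- 2L * nonmiss - n_alt
  flip <- n_alt > n_ref | (n_alt == n_ref & alt < ref)
  calls[, flip] <- 2L - calls[, flip]
  tmp <- ref[flip]; ref[flip] <- alt[flip]; alt[flip] <- tmp
  n_alt2 <- colSums(calls, na.rm = TRUE)
  n_ref2 <- 2L * colSums(!is.na(calls)) - n_alt2
  alt[n_alt2 == 0L] <- "N"
  ref[n_ref2 == 0L] <- "N"
  samples <- data.frame(
    sample_id = c(sprintf("case%04d", seq_len(nca)),
                  sprintf("ctrl%04d", seq_len(nco))),
    phenotype = c(rep("case", nca), rep("control", nco)),
    stringsAsFactors = FALSE
  )
  snps <- data.frame(
    snp_id = layout$snp_map$snp_id,
    chromosome = layout$snp_map$chromosome,
    position = layout$snp_map$position,
    allele_ref = ref, allele_alt = alt,
    stringsAsFactors = FALSE
  )
  storage.mode(calls) <- "integer"
  truth <- list(causal = data.frame(
    snp_id = layout$snp_map$snp_id[layout$causal_idx],
    gene_id = layout$causal_genes,
    odds_ratio = rep(spec$causal_or, length(layout$causal_idx)),
    f_control = f_ctrl[layout$causal_idx],
    f_case = f_case[layout$causal_idx],
    stringsAsFactors = FALSE
  ))
  list(dataset = .new_genotype_dataset(samples, snps, calls), truth = truth)
}

#' Simulate a scale-free interaction network with planted modules
#'
#' Builds a preferential-attachment background over gene identifiers (each
#' new node attaches to `attachment_edges` existing nodes with probability
#' proportional to degree), then plants each requested module by rewiring
#' the edges INSIDE its member set to the requested internal density
#' (density 1 plants a clique), leaving all edges to the rest of the
#' background intact, and adding a bridge edge if a module would otherwise
#' be disconnected from the background.  Module members are drawn from the
#' causal genes so the end-to-end pipeline exercises recovery; node ids come
#' from the gene universe so the induced-subgraph step is exercised.
#'
#' @param spec a [sim_spec()].
#' @return list with `edge_table` (data frame `node_a`, `node_b`, `score`)
#'   and `truth` (list with `nodes` and `modules`, each module a list with
#'   `members` and `density`).
#' @export
simulate_ppi <- function(spec) {
  layout <- .sim_layout(spec)
  set.seed(.substream(spec$seed, 3L))
  module_genes <- unique(unlist(lapply(layout$modules, `[[`, "members")))
  others <- setdiff(layout$annotation$gene_id, module_genes)
  n_extra <- spec$ppi_background_nodes - length(module_genes)
  if (n_extra < 0) stop("ppi_background_nodes smaller than planted modules")
  nodes <- c(module_genes, sample(others, min(n_extra, length(others))))
  nodes <- sample(nodes)   # random vertex order for preferential attachment
  g <- igraph::sample_pa(length(nodes), m = spec$attachment_edges,
                         directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  a <- nodes[el[, 1]]; b <- nodes[el[, 2]]
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  for (mod in layout$modules) {
    mem <- mod$members
    if (mod$style == "hub_spoke") {
      # strip ALL background edges touching the module, then lay down the
      # designed structure: apex adjacent to every spoke, spokes in a
      # circulant ring C_m(1, 3), one bridge from the apex to the background
      touches <- a %in% mem | b %in% mem
      a <- a[!touches]; b <- b[!touches]
      apex <- mod$apex
      spokes <- setdiff(mem, apex)
      m <- length(spokes)
      nxt <- c(2:m, 1L)
      chord <- ((seq_len(m) + 2L) %% m) + 1L
      a <- c(a, rep(apex, m), spokes, spokes)
      b <- c(b, spokes, spokes[nxt], spokes[chord])
      outside <- setdiff(nodes, mem)
      a <- c(a, apex); b <- c(b, sample(outside, 1))
    } else {
      internal <- a %in% mem & b %in% mem
      a <- a[!internal]; b <- b[!internal]
      prs <- utils::combn(sort(mem), 2)
      n_e <- round(mod$density * ncol(prs))
      sel <- sort(sample.int(ncol(prs), n_e))
      a <- c(a, prs[1, sel]); b <- c(b, prs[2, sel])
      if (!any((a %in% mem) != (b %in% mem))) {
        outside <- setdiff(nodes, mem)
        a <- c(a, mem[1]); b <- c(b, sample(outside, 1))
      }
    }
  }
  edge_table <- data.frame(node_a = a, node_b = b,
                           score = round(stats::runif(length(a), 0.15, 0.99), 3),
                           stringsAsFactors = FALSE)
  list(edge_table = edge_table,
       truth = list(nodes = sort(nodes), modules = layout$modules))
}

#' Simulate annotation gene sets with one constructed enriched term
#'
#' Builds one term engineered to overlap the designated query (the causal
#' genes) at a chosen count, plus uniformly sampled background terms, over
#' the universe of all simulated genes.  The truth records the
#' hypergeometric counts (N, K, n, k) of every term against the query.
#'
#' @param spec a [sim_spec()].
#' @param n_background number of background terms (default 20).
#' @return list with `collection` (as [read_gmt()] returns), `query` (the
#'   designated query genes) and `truth` (data frame `term_id`, `N`, `K`,
#'   `n`, `k`).
#' @export
simulate_annotation_sets <- function(spec, n_background = 20L) {
  layout <- .sim_layout(spec)
  set.seed(.substream(spec$seed, 4L))
  universe <- layout$annotation$gene_id
  query <- sort(unique(layout$causal_genes))
  N <- length(universe); n <- length(query)
  K <- max(4L, min(N, round(0.05 * N)))
  k <- min(n, K, max(3L, round(0.6 * min(n, K))))
  members <- c(sample(query, k),
               sample(setdiff(universe, query), K - k))
  collection <- list(TERM_ENRICHED = list(description = "planted enriched term",
                                          members = sort(members)))
  for (i in seq_len(n_background)) {
    sz <- sample(10:50, 1)
    collection[[sprintf("TERM_BG%03d", i)]] <-
      list(description = "background term",
           members = sort(sample(universe, min(sz, N))))
  }
  truth <- data.frame(
    term_id = names(collection),
    N = N,
    K = vapply(collection, function(t) length(t$members), 0L),
    n = n,
    k = vapply(collection, function(t) length(intersect(t$members, query)), 0L),
    stringsAsFactors = FALSE, row.names = NULL
  )
  list(collection = collection, query = query, truth = truth)
}

#' Write a genotype dataset as PLINK text PED/MAP
#'
#' @param dataset a `genotype_dataset`.
#' @param ped_path,map_path output paths.
#' @return invisible character vector of the two paths.
#' @export
write_ped_map <- function(dataset, ped_path, map_path) {
  map <- sprintf("%s\t%s\t0\t%d", dataset$snps$chromosome,
                 dataset$snps$snp_id, dataset$snps$position)
  writeLines(map, map_path)
  ref <- dataset$snps$allele_ref
  alt <- dataset$snps$allele_alt
  n <- nrow(dataset$samples)
  lines <- character(n)
  for (i in seq_len(n)) {
    g <- dataset$calls[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, alt, ref))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, alt, ref))
    pheno <- if (dataset$samples$phenotype[i] == "case") "2" else "1"
    lines[i] <- paste(c(sprintf("F%04d", i), dataset$samples$sample_id[i],
                        "0", "0", "1", pheno, rbind(a1, a2)), collapse = " ")
  }
  writeLines(lines, ped_path)
  invisible(c(ped_path, map_path))
}

#' Write gene annotation as BED3+1 (0-based half-open)
#' @param annotation gene annotation data frame (1-based inclusive).
#' @param path output path.
#' @return invisible path.
#' @export
write_gene_bed <- function(annotation, path) {
  writeLines(sprintf("%s\t%d\t%d\t%s", annotation$chromosome,
                     annotation$start - 1L, annotation$end,
                     annotation$gene_id), path)
  invisible(path)
}

#' Write an edge table as whitespace-delimited text
#' @param edge_table data frame `node_a`, `node_b`, optional `score`.
#' @param path output path.
#' @return invisible path.
#' @export
write_edge_list <- function(edge_table, path) {
  if (!is.null(edge_table$score) && !all(is.na(edge_table$score))) {
    writeLines(sprintf("%s\t%s\t%.3f", edge_table$node_a, edge_table$node_b,
                       edge_table$score), path)
  } else {
    writeLines(sprintf("%s\t%s", edge_table$node_a, edge_table$node_b), path)
  }
  invisible(path)
}

#' Write an annotation collection as GMT
#' @param collection named list as from [read_gmt()].
#' @param path output path.
#' @return invisible path.
#' @export
write_gmt <- function(collection, path) {
  lines <- vapply(names(collection), function(nm) {
    t <- collection[[nm]]
    paste(c(nm, t$description, t$members), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Generate and write a complete synthetic study
#'
#' Produces every input the pipeline consumes (PED/MAP genotypes, BED gene
#' annotation, interaction edge list, GMT annotation sets) plus a ground
#' truth JSON in `dir`.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory (created if missing).
#' @return invisible list of file paths and in-memory truth objects.
#' @export
simulate_study <- function(spec, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  geno <- simulate_genotypes(spec)
  ann <- simulate_gene_annotation(spec)
  ppi <- simulate_ppi(spec)
  sets <- simulate_annotation_sets(spec)
  paths <- list(
    ped = file.path(dir, "study.ped"),
    map = file.path(dir, "study.map"),
    bed = file.path(dir, "genes.bed"),
    edges = file.path(dir, "ppi.tsv"),
    gmt = file.path(dir, "sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_ped_map(geno$dataset, paths$ped, paths$map)
  write_gene_bed(ann$annotation, paths$bed)
  write_edge_list(ppi$edge_table, paths$edges)
  write_gmt(sets$collection, paths$gmt)
  truth <- list(
    seed = spec$seed,
    causal = geno$truth$causal,
    snp_map = ann$snp_map,
    ppi_nodes = ppi$truth$nodes,
    modules = ppi$truth$modules,
    enrichment = sets$truth,
    query = sets$query
  )
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(paths, list(truth_data = truth)))
}
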
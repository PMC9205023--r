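# Readers and writers for the on-disk formats: CDS FASTA, gene
# coordinate tables (GFF3 or 5-column TSV), homolog pair tables, block
# and call tables, YAML configuration and JSON truth/fit reports.
# All tabular outputs are tab-separated with a '#'-prefixed header line.

#' Write/read a TSV table with a '#'-prefixed header
#'
#' @param df data.frame to write.
#' @param path File path.
#' @return `readTsv` returns a data.frame.
#' @export
writeTsv <- function(df, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df))
    write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                col.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname writeTsv
#' @export
readTsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1)
  cols <- strsplit(sub("^#", "", first), "\t")[[1]]
  df <- read.delim(path, header = FALSE, skip = 1, sep = "\t",
                   col.names = cols, comment.char = "",
                   stringsAsFactors = FALSE)
  df
}

#' Construct a GeneCatalog
#'
#' @param coords data.frame with columns `gene_id`, `chromosome`,
#'   `start`, `end`, `strand` (1-based inclusive coordinates).
#' @param cds Named character vector or DNAStringSet of CDS sequences.
#' @param genome Genome label.
#' @return A [GeneCatalog-class]; `order_index` is assigned per
#'   chromosome by ascending start.
#' @export
GeneCatalog <- function(coords, cds, genome = "genome") {
  cds <- Biostrings::DNAStringSet(cds)
  if (anyDuplicated(coords$gene_id))
    stop("duplicate gene_id in coordinate table")
  if (anyDuplicated(names(cds)))
    stop("duplicate gene_id in CDS set")
  keep <- coords$gene_id %in% names(cds)
  if (any(!keep))
    warning(sum(!keep), " gene(s) lack a CDS and were dropped")
  orphan <- !(names(cds) %in% coords$gene_id)
  if (any(orphan))
    warning(sum(orphan), " CDS without coordinates dropped")
  coords <- coords[keep, , drop = FALSE]
  cds <- cds[coords$gene_id]
  bad <- Biostrings::width(cds) %% 3 != 0
  if (any(bad)) {
    warning(sum(bad), " gene(s) with CDS length not divisible by 3 dropped")
    coords <- coords[!bad, , drop = FALSE]
    cds <- cds[coords$gene_id]
  }
  ord <- order(coords$chromosome, coords$start)
  coords <- coords[ord, , drop = FALSE]
  cds <- cds[coords$gene_id]
  oi <- unlist(lapply(split(seq_len(nrow(coords)), coords$chromosome),
                      function(i) seq_along(i) - 1L), use.names = FALSE)
  gr <- GenomicRanges::GRanges(
    seqnames = coords$chromosome,
    ranges = IRanges::IRanges(start = coords$start, end = coords$end),
    strand = ifelse(coords$strand %in% c("+", "-"), coords$strand, "*"))
  gr$gene_id <- coords$gene_id
  gr$order_index <- oi
  methods::new("GeneCatalog", genes = gr, cds = cds, genome = genome)
}

.readCoords <- function(coords_path) {
  if (grepl("\\.gff3?$", coords_path, ignore.case = TRUE)) {
    if (!requireNamespace("rtracklayer", quietly = TRUE))
      stop("reading GFF3 requires the rtracklayer package")
    gr <- rtracklayer::import(coords_path)
    gr <- gr[gr$type %in% c("gene", "mRNA")]
    id <- if (!is.null(gr$ID)) gr$ID else gr$Name
    data.frame(gene_id = as.character(id),
               chromosome = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr),
               end = GenomicRanges::end(gr),
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
  } else {
    df <- readTsv(coords_path)
    need <- c("gene_id", "chromosome", "start", "end")
    if (!all(need %in% names(df)))
      stop("coordinate table must have columns ",
           paste(need, collapse = ", "))
    if (is.null(df$strand)) df$strand <- "*"
    df
  }
}

#' Read a gene catalog from CDS FASTA plus a coordinate file
#'
#' Coordinates may be GFF3 (`.gff`/`.gff3`; gene or mRNA features with
#' an `ID` attribute) or a TSV with columns `gene_id`, `chromosome`,
#' `start`, `end` and optionally `strand`. CDS sequences are assumed
#' strand-resolved. Genes missing from either file, or whose CDS length
#' is not divisible by 3, are reported and dropped; duplicated ids are
#' an error.
#'
#' @param fasta_path CDS FASTA.
#' @param coords_path Coordinate file.
#' @param genome Genome label.
#' @return A [GeneCatalog-class].
#' @export
readGeneCatalog <- function(fasta_path, coords_path, genome = "genome") {
  if (!file.exists(fasta_path)) stop("input file not found: ", fasta_path)
  cds <- Biostrings::readDNAStringSet(fasta_path)
  names(cds) <- sub("\\s.*$", "", names(cds))
  coords <- .readCoords(coords_path)
  GeneCatalog(coords, cds, genome = genome)
}

#' Write a gene catalog to CDS FASTA plus a coordinate TSV
#'
#' @param catalog A [GeneCatalog-class].
#' @param fasta_path,coords_path Output paths.
#' @export
writeGeneCatalog <- function(catalog, fasta_path, coords_path) {
  Biostrings::writeXStringSet(cdsSeqs(catalog), fasta_path)
  gr <- geneRanges(catalog)
  writeTsv(data.frame(gene_id = gr$gene_id,
                      chromosome = as.character(GenomicRanges::seqnames(gr)),
                      start = GenomicRanges::start(gr),
                      end = GenomicRanges::end(gr),
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE),
           coords_path)
  invisible(catalog)
}

#' Read a homolog pair table
#'
#' Expects a TSV whose first two columns are gene ids (header optional;
#' recognized names `gene_a`/`gene_b`). Optional `score` and `evalue`
#' columns are kept and, when present, can be used as input filters by
#' the collinearity stage. Pairs are canonicalized lexicographically and
#' de-duplicated; self-pairs are dropped with a warning.
#'
#' @param path TSV path.
#' @return data.frame `gene_a`, `gene_b` (+ `score`, `evalue` if present).
#' @export
readPairTable <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  first <- readLines(path, n = 1)
  df <- if (startsWith(first, "#")) readTsv(path) else
    read.delim(path, header = grepl("gene", first, ignore.case = TRUE),
               sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("pair table needs at least two columns")
  names(df)[1:2] <- c("gene_a", "gene_b")
  canonicalizePairs(df)
}

#' Canonicalize a homolog pair table
#'
#' @param df data.frame with `gene_a`, `gene_b` in its first columns.
#' @return The table with each pair ordered lexicographically,
#'   self-pairs removed (with a warning) and duplicates collapsed.
#' @export
canonicalizePairs <- function(df) {
  a <- as.character(df$gene_a); b <- as.character(df$gene_b)
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-pair(s) dropped")
    df <- df[!self, , drop = FALSE]
    a <- a[!self]; b <- b[!self]
  }
  df$gene_a <- pmin(a, b)
  df$gene_b <- pmax(a, b)
  df[!duplicated(df[, c("gene_a", "gene_b")]), , drop = FALSE]
}

#' Write a homolog pair table
#' @param df data.frame with `gene_a`, `gene_b` (+ extras).
#' @param path Output TSV path.
#' @export
writePairTable <- function(df, path) writeTsv(df, path)

#' Write/read a collinear block set as a single long-format TSV
#'
#' Block summary rows (`row_type = "block"`) are followed by their
#' anchor rows (`row_type = "anchor"`).
#'
#' @param blockset A [CollinearBlockSet-class].
#' @param path File path.
#' @export
writeBlocks <- function(blockset, path) {
  b <- blockTable(blockset)
  a <- anchorTable(blockset)
  long <- rbind(
    data.frame(row_type = "block", block_id = b$block_id,
               f1 = b$genome_a, f2 = b$genome_b, f3 = b$chrom_a,
               f4 = b$chrom_b, f5 = b$orientation, f6 = b$n_anchors,
               f7 = b$median_ks, f8 = b$event_label,
               stringsAsFactors = FALSE),
    data.frame(row_type = "anchor", block_id = a$block_id, f1 = a$gene_a,
               f2 = a$gene_b, f3 = a$order_a, f4 = a$order_b, f5 = NA,
               f6 = NA, f7 = NA, f8 = NA, stringsAsFactors = FALSE))
  long <- long[order(match(long$block_id, b$block_id),
                     long$row_type == "anchor"), ]
  writeTsv(long, path)
  invisible(blockset)
}

#' @rdname writeBlocks
#' @export
readBlocks <- function(path) {
  long <- readTsv(path)
  bl <- long[long$row_type == "block", ]
  an <- long[long$row_type == "anchor", ]
  blocks <- data.frame(block_id = bl$block_id, genome_a = bl$f1,
                       genome_b = bl$f2, chrom_a = bl$f3, chrom_b = bl$f4,
                       orientation = bl$f5,
                       n_anchors = as.integer(bl$f6),
                       median_ks = suppressWarnings(as.numeric(bl$f7)),
                       event_label = bl$f8, stringsAsFactors = FALSE)
  anchors <- data.frame(block_id = an$block_id, gene_a = an$f1,
                        gene_b = an$f2, order_a = as.integer(an$f3),
                        order_b = as.integer(an$f4),
                        stringsAsFactors = FALSE)
  methods::new("CollinearBlockSet", blocks = blocks, anchors = anchors)
}

#' Pipeline configuration with the published defaults
#'
#' Central record of every tunable of the pipeline, with the published
#' operating values as defaults: collinearity max gap 50 intervening
#' genes, minimum block length 4 anchors, gene-family size cutoff 50,
#' Ks kernel bandwidth 0.05, mixture R-squared threshold 0.95, minimum
#' conversion tract 10 nt, 1000 bootstrap replicates, significance level
#' 0.05 and expression fold-change cutoff 2.
#'
#' @param max_gap,min_block_len,family_size_cutoff Collinearity stage.
#' @param kde_bandwidth,r2_threshold Ks mixture stage.
#' @param min_tract_len,bootstrap_B,alpha Conversion stage.
#' @param fold_cutoff,tpm_pseudocount Expression stage.
#' @param rng_seed Seed recorded and applied by the CLI subcommands.
#' @return Named list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(max_gap = 50, min_block_len = 4,
                           family_size_cutoff = 50, kde_bandwidth = 0.05,
                           r2_threshold = 0.95, min_tract_len = 10,
                           bootstrap_B = 1000, alpha = 0.05,
                           fold_cutoff = 2.0, tpm_pseudocount = 0.1,
                           rng_seed = 1L) {
  structure(list(max_gap = max_gap, min_block_len = min_block_len,
                 family_size_cutoff = family_size_cutoff,
                 kde_bandwidth = kde_bandwidth,
                 r2_threshold = r2_threshold,
                 min_tract_len = min_tract_len,
                 bootstrap_B = bootstrap_B, alpha = alpha,
                 fold_cutoff = fold_cutoff,
                 tpm_pseudocount = tpm_pseudocount,
                 rng_seed = rng_seed), class = "PipelineConfig")
}

#' Read/write the pipeline configuration as YAML
#' @param path YAML path.
#' @param config A [pipelineConfig()].
#' @export
readConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipelineConfig, vals[names(vals) %in% names(formals(pipelineConfig))])
}

#' @rdname readConfig
#' @export
writeConfig <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(config)
}

#' Write/read a simulation truth record as JSON
#' @param truth data.frame of implanted events.
#' @param path JSON path.
#' @export
writeSimTruth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "rows", na = "null",
                       auto_unbox = TRUE, digits = NA)
  invisible(truth)
}

#' @rdname writeSimTruth
#' @export
readSimTruth <- function(path) {
  df <- jsonlite::fromJSON(path)
  as.data.frame(df, stringsAsFactors = FALSE)
}
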
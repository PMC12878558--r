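#' Read an all-sites VCF into a variant table
#'
#' Supports the dialect written by [write_allsites_vcf()] and by standard
#' all-sites callers: bi-allelic SNP records plus invariant records with ALT
#' "." (or no ALT), FORMAT fields GT (required) and optionally DP and AD.
#' Multi-allelic records are rejected. Genotypes "./." (or ".") load as
#' missing.
#'
#' @param path path to a VCF (v4.x, plain text or gzipped)
#' @param contig_lengths optional named vector overriding the `##contig`
#'   header lines
#' @return a [variant_table()]
#' @export
read_allsites_vcf <- function(path, contig_lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- character(0)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con), add = TRUE)
  repeat {
    ln <- readLines(con, n = 1L)
    if (!length(ln)) stop("malformed VCF: no #CHROM header line in ", path)
    if (startsWith(ln, "##")) { hdr <- c(hdr, ln); next }
    if (startsWith(ln, "#CHROM")) { colhdr <- ln; break }
    stop("malformed VCF: unexpected line before header: ", substr(ln, 1, 60))
  }
  cols <- strsplit(sub("^#", "", colhdr), "\t", fixed = TRUE)[[1]]
  if (length(cols) < 10L) stop("VCF has no sample columns")
  samples <- cols[-(1:9)]
  dt <- data.table::fread(text = readLines(con), header = FALSE, sep = "\t",
                          col.names = cols, colClasses = list(character = 1))
  if (!nrow(dt)) stop("VCF contains no records")
  nl <- length(hdr) + 1L
  if (ncol(dt) != length(cols))
    stop("malformed VCF: wrong column count near line ", nl + 1L)

  alt <- as.character(dt$ALT)
  multi <- grepl(",", alt, fixed = TRUE)
  if (any(multi)) {
    i <- which(multi)[1]
    stop(sprintf("multi-allelic site not supported: %s:%s (ALT=%s)",
                 dt$CHROM[i], dt$POS[i], alt[i]))
  }
  alt[alt == "." | alt == ""] <- NA_character_
  qual <- suppressWarnings(as.numeric(dt$QUAL))

  fmt <- strsplit(as.character(dt$FORMAT), ":", fixed = TRUE)
  fmt1 <- fmt[[1]]
  if (!all(vapply(fmt, function(f) identical(f, fmt1), TRUE)))
    stop("heterogeneous FORMAT strings are not supported")
  i_gt <- match("GT", fmt1); i_dp <- match("DP", fmt1); i_ad <- match("AD", fmt1)
  if (is.na(i_gt)) stop("FORMAT lacks GT")

  nsamp <- length(samples); nsite <- nrow(dt)
  gt <- matrix(NA_integer_, nsite, nsamp)
  dp <- if (!is.na(i_dp)) matrix(NA_integer_, nsite, nsamp) else NULL
  ad <- if (!is.na(i_ad)) matrix(NA_integer_, nsite, nsamp) else NULL
  gt_code <- c("0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L,
               "1|0" = 1L, "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 2L)
  for (j in seq_len(nsamp)) {
    f <- strsplit(as.character(dt[[9L + j]]), ":", fixed = TRUE)
    gtok <- vapply(f, `[`, "", i_gt)
    g <- gt_code[gtok]
    bad <- is.na(g) & !(gtok %in% c("./.", ".", ".|."))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("unparseable or out-of-range GT '%s' at %s:%s (sample %s)",
                   gtok[i], dt$CHROM[i], dt$POS[i], samples[j]))
    }
    gt[, j] <- unname(g)
    if (!is.null(dp)) {
      d <- vapply(f, function(x) if (length(x) >= i_dp) x[i_dp] else ".", "")
      dp[, j] <- suppressWarnings(as.integer(d))
    }
    if (!is.null(ad)) {
      a <- vapply(f, function(x) if (length(x) >= i_ad) x[i_ad] else ".", "")
      ad[, j] <- suppressWarnings(
        as.integer(vapply(strsplit(a, ",", fixed = TRUE),
                          function(x) if (length(x) >= 2) x[2] else NA_character_, "")))
    }
  }
  # genotypes composed of site alleles: invariant sites cannot carry alt
  inv <- is.na(alt)
  if (any(inv)) {
    off <- which(inv & rowSums(gt > 0L, na.rm = TRUE) > 0L)
    if (length(off))
      stop(sprintf("invariant site %s:%s carries a non-ref genotype",
                   dt$CHROM[off[1]], dt$POS[off[1]]))
  }
  if (is.null(contig_lengths)) {
    cl_ln <- grep("^##contig=", hdr, value = TRUE)
    if (length(cl_ln)) {
      ids <- sub(".*ID=([^,>]+).*", "\\1", cl_ln)
      lens <- suppressWarnings(as.numeric(sub(".*length=([0-9]+).*", "\\1", cl_ln)))
      if (!anyNA(lens)) contig_lengths <- setNames(lens, ids)
    }
  }
  sites <- data.frame(chrom = as.character(dt$CHROM),
                      pos = as.integer(dt$POS),
                      ref = as.character(dt$REF), alt = alt, qual = qual,
                      stringsAsFactors = FALSE)
  variant_table(sites, gt, samples, dp = dp, ad_alt = ad,
                contig_lengths = contig_lengths)
}

#' Write a variant table as an all-sites VCF
#'
#' Emits VCF v4.2 with FORMAT `GT:DP:AD` (or `GT` when depths are absent),
#' "." ALT for invariant sites and "./." for missing genotypes, so that a
#' write-then-read round trip is the identity on GT/DP/AD/QUAL.
#'
#' @param table a [variant_table()]
#' @param path output path (".gz" suffix gives gzip compression)
#' @return `path`, invisibly
#' @export
write_allsites_vcf <- function(table, path) {
  stopifnot(inherits(table, "variant_table"))
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(table$contig_lengths),
                   as.integer(table$contig_lengths)),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  has_dp <- !is.null(table$dp); has_ad <- !is.null(table$ad_alt)
  if (has_dp) hdr <- c(hdr, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  if (has_ad) hdr <- c(hdr, "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  fmt <- paste(c("GT", if (has_dp) "DP", if (has_ad) "AD"), collapse = ":")
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                        "INFO", "FORMAT", table$samples), collapse = "\t"))
  gt_str <- matrix(c("0/0", "0/1", "1/1")[table$gt + 1L], nrow = n_sites(table))
  gt_str[is.na(table$gt)] <- "./."
  cells <- gt_str
  if (has_dp) {
    d <- ifelse(is.na(table$dp), ".", as.character(table$dp))
    cells <- matrix(paste(cells, d, sep = ":"), nrow = nrow(cells))
  }
  if (has_ad) {
    ref_d <- table$dp - table$ad_alt
    a <- ifelse(is.na(table$ad_alt), ".",
                paste0(ifelse(is.na(ref_d), ".", ref_d), ",", table$ad_alt))
    cells <- matrix(paste(cells, a, sep = ":"), nrow = nrow(cells))
  }
  alt <- table$sites$alt
  alt[is.na(alt)] <- "."
  qual <- ifelse(is.na(table$sites$qual), ".",
                 sub("\\.0+$", "", format(table$sites$qual, trim = TRUE,
                                          scientific = FALSE)))
  fixed <- paste(table$sites$chrom, table$sites$pos, ".", table$sites$ref,
                 alt, qual, "PASS", ".", fmt, sep = "\t")
  body <- paste(fixed, apply(cells, 1L, paste, collapse = "\t"), sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  writeLines(c(hdr, body), con)
  close(con)
  invisible(path)
}

#' Write/read helper tables (popmap, coordinates, environment)
#'
#' Plain TSV with a header row; `read_popmap` checks the two required
#' columns are present.
#'
#' @param x data.frame to write
#' @param path file path
#' @return `path` (writers) or a data.frame (readers)
#' @export
write_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_popmap <- function(path) {
  pm <- as.data.frame(data.table::fread(path))
  if (!all(c("sample", "population") %in% names(pm)))
    stop("popmap needs columns 'sample' and 'population'")
  pm
}
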
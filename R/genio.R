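#' Write a GRM in GCTA binary format
#'
#' Writes the lower triangle (including the diagonal) of a genetic
#' relationship matrix as 4-byte little-endian reals in row-major pair
#' order (1,1), (2,1), (2,2), (3,1), ... to `<prefix>.grm.bin`, the ids as
#' a two-column text table to `<prefix>.grm.id`, and (optionally) the
#' per-pair number of contributing SNPs to `<prefix>.grm.N.bin` in the same
#' layout — the de-facto binary convention for relationship matrices.
#'
#' @param grm a [grm()] object (symmetric, finite, unique ids).
#' @param prefix output path prefix.
#' @param write_n also write the `.grm.N.bin` companion (default TRUE when
#'   the object carries `m_used`).
#' @param overwrite overwrite existing files (default FALSE).
#' @return invisibly, the paths written.
#' @export
write_grm <- function(grm, prefix, write_n = TRUE, overwrite = FALSE) {
  stopifnot(inherits(grm, "grm"))
  A <- grm$A
  if (any(!is.finite(A))) stop_param("GRM contains non-finite entries")
  if (max(abs(A - t(A))) > 1e-8) stop_param("GRM must be symmetric")
  n <- nrow(A)
  paths <- paste0(prefix, c(".grm.bin", ".grm.id", ".grm.N.bin"))
  if (!overwrite && any(file.exists(paths[1:2]))) {
    stop_param("output files exist; use overwrite = TRUE")
  }
  tri <- A[lower.tri(A, diag = TRUE)]
  # lower.tri is column-major (1,1),(2,1),...,(n,1),(2,2),...; the archive
  # wants row-major over (i, j<=i): sort by row index (stable, so columns
  # stay increasing within a row)
  ord <- order(unlist(lapply(seq_len(n), function(j) seq(j, n))))
  con <- file(paths[1], "wb")
  writeBin(as.numeric(tri[ord]), con, size = 4L, endian = "little")
  close(con)
  utils::write.table(data.frame(grm$fid, grm$iid),
                     paths[2], quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  written <- paths[1:2]
  if (write_n && !is.null(grm$m_used)) {
    con <- file(paths[3], "wb")
    writeBin(rep(as.numeric(grm$m_used), n * (n + 1) / 2), con,
             size = 4L, endian = "little")
    close(con)
    written <- paths
  }
  invisible(written)
}

#' Read a GRM from GCTA binary format
#'
#' @param prefix path prefix of `<prefix>.grm.bin` / `<prefix>.grm.id`.
#' @return a [grm()] object; `m_used` is taken from `<prefix>.grm.N.bin`
#'   when present (rounded mean of the per-pair counts), otherwise NA.
#' @export
read_grm <- function(prefix) {
  bin <- paste0(prefix, ".grm.bin"); idf <- paste0(prefix, ".grm.id")
  if (!file.exists(bin) || !file.exists(idf)) {
    stop_param("missing .grm.bin or .grm.id for prefix ", prefix)
  }
  ids <- utils::read.table(idf, colClasses = "character")
  n <- nrow(ids)
  if (anyDuplicated(paste(ids[[1]], ids[[2]]))) {
    stop_param("duplicate (fid, iid) in .grm.id")
  }
  n_exp <- n * (n + 1) / 2
  sz <- file.info(bin)$size
  if (sz != 4 * n_exp) {
    stop_param(sprintf(
      "corrupt GRM archive: %d bytes in .grm.bin, expected %d for %d ids",
      sz, 4 * n_exp, n))
  }
  con <- file(bin, "rb")
  vals <- readBin(con, "numeric", n = n_exp, size = 4L, endian = "little")
  close(con)
  A <- matrix(0, n, n)
  # fill row-major lower triangle
  idx <- cbind(rep(seq_len(n), times = seq_len(n)),
               unlist(lapply(seq_len(n), seq_len)))
  A[idx] <- vals
  A[upper.tri(A)] <- t(A)[upper.tri(A)]
  m_used <- NA_real_
  nbin <- paste0(prefix, ".grm.N.bin")
  if (file.exists(nbin)) {
    con <- file(nbin, "rb")
    nv <- readBin(con, "numeric", n = n_exp, size = 4L, endian = "little")
    close(con)
    m_used <- round(mean(nv))
  }
  new_grm(A, fid = ids[[1]], iid = ids[[2]], m_used = m_used)
}

#' Write genotypes as PLINK-style text
#'
#' `format = "traw"` writes transposed dosage text (one row per SNP, header
#' `CHR SNP (C)M POS COUNTED ALT` then one `FID_IID` column per individual,
#' dosages 0/1/2, missing as NA). `format = "ped"` writes a `.ped`/`.map`
#' pair with the counted allele coded `A`, the other `B`, and missing
#' genotypes as `0 0`.
#'
#' @param G a [genotype_matrix()].
#' @param path output file path (for `ped`, the `.map` file is written next
#'   to it with the extension swapped).
#' @param format `"traw"` or `"ped"`.
#' @return invisibly, the paths written.
#' @export
write_genotypes <- function(G, path, format = c("traw", "ped")) {
  format <- match.arg(format)
  stopifnot(inherits(G, "genotype_matrix"))
  m <- ncol(G$dosages)
  if (format == "traw") {
    df <- data.frame(CHR = 1L, SNP = G$snp_ids, `(C)M` = 0, POS = seq_len(m),
                     COUNTED = "A", ALT = "B", check.names = FALSE,
                     stringsAsFactors = FALSE)
    df <- cbind(df, as.data.frame(t(G$dosages)))
    names(df)[-(1:6)] <- paste(G$fid, G$iid, sep = "_")
    utils::write.table(df, path, quote = FALSE, sep = "\t",
                       row.names = FALSE, na = "NA")
    return(invisible(path))
  }
  map_path <- sub("\\.ped$", ".map", path)
  if (identical(map_path, path)) map_path <- paste0(path, ".map")
  allele_txt <- function(x) {
    out <- matrix("0 0", nrow(x), ncol(x))
    out[!is.na(x) & x == 0L] <- "B B"
    out[!is.na(x) & x == 1L] <- "A B"
    out[!is.na(x) & x == 2L] <- "A A"
    out
  }
  ped <- cbind(G$fid, G$iid, "0", "0", "0", "-9", allele_txt(G$dosages))
  utils::write.table(ped, path, quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(data.frame(1L, G$snp_ids, 0, seq_len(m)), map_path,
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(path, map_path))
}

#' Read genotypes from PLINK-style text
#'
#' Individuals are returned in file order, never reordered. For `ped`
#' input, per SNP the counted allele is the lexicographically smallest
#' non-missing allele code (so files written by [write_genotypes()] round
#' trip exactly); `0` denotes a missing allele and any half-missing call is
#' treated as fully missing.
#'
#' @param path file path (`.traw`, or `.ped` with its `.map` alongside).
#' @param format `"traw"` or `"ped"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("traw", "ped")) {
  format <- match.arg(format)
  if (format == "traw") {
    df <- utils::read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE, stringsAsFactors = FALSE)
    need <- c("CHR", "SNP", "(C)M", "POS", "COUNTED", "ALT")
    if (!all(need %in% names(df)[1:6])) {
      stop_param("not a recognised traw header")
    }
    dos <- t(as.matrix(df[, -(1:6), drop = FALSE]))
    if (!all(dos %in% c(0, 1, 2) | is.na(dos))) {
      stop_param("traw dosages must be 0/1/2 or NA")
    }
    ids <- rownames(dos)
    fid <- sub("_[^_]*$", "", ids)
    iid <- sub("^.*_", "", ids)
    return(genotype_matrix(dos, fid, iid, snp_ids = df$SNP))
  }
  lines <- readLines(path)
  toks <- strsplit(trimws(lines), "[ \t]+")
  len <- lengths(toks)
  if (length(unique(len)) != 1) stop_param("ragged .ped rows")
  if ((len[1] - 6) %% 2 != 0 || len[1] < 8) stop_param("malformed .ped row")
  m <- (len[1] - 6) / 2
  tab <- do.call(rbind, toks)
  a1 <- tab[, 6 + 2 * seq_len(m) - 1, drop = FALSE]
  a2 <- tab[, 6 + 2 * seq_len(m), drop = FALSE]
  dos <- matrix(NA_integer_, nrow(tab), m)
  for (j in seq_len(m)) {
    al <- c(a1[, j], a2[, j])
    codes <- sort(setdiff(unique(al), "0"))
    if (length(codes) > 2) stop_param("non-biallelic codes in .ped column ", j)
    counted <- codes[1]
    miss <- a1[, j] == "0" | a2[, j] == "0"
    dos[, j] <- (a1[, j] == counted) + (a2[, j] == counted)
    dos[miss, j] <- NA_integer_
  }
  map_path <- sub("\\.ped$", ".map", path)
  snp_ids <- if (file.exists(map_path)) {
    utils::read.table(map_path, colClasses = "character")[[2]]
  } else NULL
  genotype_matrix(dos, fid = tab[, 1], iid = tab[, 2], snp_ids = snp_ids)
}

#' Read or write a whitespace-delimited phenotype table
#'
#' Columns `FID IID value`; both `NA` and `-9` on disk denote a missing
#' phenotype and map to the single internal sentinel `NA`.
#'
#' @param path file path.
#' @return `read_phenotype`: data.frame `fid`, `iid`, `phenotype`.
#' @export
read_phenotype <- function(path) {
  df <- utils::read.table(path, header = FALSE,
                          col.names = c("fid", "iid", "phenotype"),
                          colClasses = c("character", "character", "character"),
                          na.strings = c("NA", "-9"))
  df$phenotype <- as.numeric(df$phenotype)
  df
}

#' @rdname read_phenotype
#' @param phen data.frame with columns `fid`, `iid`, `phenotype`.
#' @export
write_phenotype <- function(phen, path) {
  utils::write.table(phen[, c("fid", "iid", "phenotype")], path,
                     quote = FALSE, sep = " ", row.names = FALSE,
                     col.names = FALSE, na = "NA")
  invisible(path)
}

#' Read or write a twin-pair table
#'
#' Tab-delimited with header `pair_id zygosity trait1 trait2
#' genotyped_twin`.
#'
#' @param path file path.
#' @return `read_twin_table`: a `twin_cohort` without genotypes.
#' @export
read_twin_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pair_id", "zygosity", "trait1", "trait2", "genotyped_twin")
  if (!all(need %in% names(df))) stop_param("missing twin-table columns")
  if (!all(df$zygosity %in% c("MZ", "DZ"))) {
    stop_param("zygosity must be MZ or DZ")
  }
  structure(list(pairs = df[, need], genotypes = NULL, effects = NULL),
            class = "twin_cohort")
}

#' @rdname read_twin_table
#' @param cohort a `twin_cohort`.
#' @export
write_twin_table <- function(cohort, path) {
  utils::write.table(cohort$pairs, path, quote = FALSE, sep = "\t",
                     row.names = FALSE)
  invisible(path)
}
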
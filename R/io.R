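# Readers/writers for the standard formats the pipeline touches: TSV
# matrices, FASTA promoter/protein sets, MEME-minimal motif libraries, GMT
# gene sets and edge tables. All readers validate strictly and reject rather
# than coerce malformed input.

#' Read a genes x samples matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Row and column order are preserved.
#'
#' @param path Path to a tab-separated file.
#' @param integer_mode If TRUE, require all values to be whole numbers
#'   (counts) and return an integer-valued matrix.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix <- function(path, integer_mode = FALSE) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop2("matrix file ", path, ": need header plus >=1 row")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1L]]
  samples <- header[-1L]
  if (anyDuplicated(samples)) stop2("matrix file: duplicate sample ids")
  ncol_exp <- length(header)
  body <- fields[-1L]
  genes <- character(length(body))
  vals <- matrix(NA_real_, nrow = length(body), ncol = length(samples))
  for (i in seq_along(body)) {
    row <- body[[i]]
    if (length(row) != ncol_exp)
      stop2("matrix file line ", i + 1L, ": expected ", ncol_exp,
            " fields, got ", length(row))
    genes[i] <- row[1L]
    v <- suppressWarnings(as.numeric(row[-1L]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1L]
      stop2("matrix file line ", i + 1L, ", column ", bad + 1L,
            ": non-numeric cell '", row[bad + 1L], "'")
    }
    vals[i, ] <- v
  }
  if (anyDuplicated(genes)) stop2("matrix file: duplicate gene ids")
  if (integer_mode && any(vals != round(vals)))
    stop2("matrix file: non-integer value in integer mode")
  dimnames(vals) <- list(genes, samples)
  if (!all(is.finite(vals))) stop2("matrix file: non-finite values")
  vals
}

#' Write a matrix as TSV (inverse of read_matrix)
#'
#' @param x Numeric matrix with dimnames.
#' @param path Output path.
#' @param id_col Name of the first (gene id) column in the header.
#' @export
write_matrix <- function(x, path, id_col = "gene_id") {
  check_matrix(x)
  header <- paste(c(id_col, colnames(x)), collapse = "\t")
  rows <- vapply(seq_len(nrow(x)), function(i)
    paste(c(rownames(x)[i], format(x[i, ], digits = 15, trim = TRUE,
                                   scientific = FALSE)), collapse = "\t"),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' Read a DNA FASTA file into a named character vector
#'
#' Ids are the token before the first whitespace in each header; sequences
#' are uppercased. Only A, C, G, T and N are accepted.
#'
#' @param path Path to a FASTA file (records may be line-wrapped).
#' @return Named character vector of uppercase sequences.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (anyDuplicated(ids))
    stop2("FASTA: duplicate id '", ids[duplicated(ids)][1L], "'")
  if (any(nchar(seqs) == 0L))
    stop2("FASTA: empty sequence for '", ids[nchar(seqs) == 0L][1L], "'")
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop2("FASTA: illegal character in '", ids[bad][1L],
          "' (only ACGTN allowed)")
  stats::setNames(seqs, ids)
}

#' Write a named character vector of sequences as FASTA
#' @param seqs Named character vector.
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path, width = 70L)
  invisible(path)
}

#' Read a MEME minimal-format motif library
#'
#' Parses "MEME version", "ALPHABET= ACGT", an optional "Background letter
#' frequencies" block, and one or more MOTIF blocks each carrying a
#' letter-probability matrix. Each motif becomes a PWM via [build_pwm()],
#' using the file background when present (else uniform).
#'
#' @param path Path to a MEME minimal file.
#' @param pseudocount Regularization passed to [build_pwm()].
#' @return A list of `pwm` objects, named by motif id.
#' @export
read_meme <- function(path, pseudocount = 0.001) {
  lines <- trimws(readLines(path))
  if (!any(grepl("^MEME version", lines)))
    stop2("MEME file: missing 'MEME version' line")
  alpha <- grep("^ALPHABET", lines, value = TRUE)
  if (length(alpha) == 0L) stop2("MEME file: missing ALPHABET line")
  if (!grepl("ACGT", gsub("[ =]", "", alpha[1L])))
    stop2("MEME file: alphabet must be ACGT")
  background <- c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
  bg_i <- grep("^Background letter frequencies", lines)
  if (length(bg_i)) {
    toks <- strsplit(lines[bg_i[1L] + 1L], "\\s+")[[1L]]
    if (length(toks) < 8L) stop2("MEME file: malformed background line")
    freqs <- as.numeric(toks[c(FALSE, TRUE)])
    names(freqs) <- toks[c(TRUE, FALSE)]
    background <- freqs[c("A", "C", "G", "T")]
    if (anyNA(background)) stop2("MEME file: background must list A C G T")
  }
  motif_i <- grep("^MOTIF ", lines)
  if (length(motif_i) == 0L) stop2("MEME file: no MOTIF blocks")
  pwms <- list()
  for (mi in motif_i) {
    id <- strsplit(lines[mi], "\\s+")[[1L]][2L]
    lp <- grep("^letter-probability matrix", lines[seq(mi, length(lines))])[1L]
    if (is.na(lp)) stop2("MEME file: motif ", id,
                         " missing letter-probability matrix")
    lp <- mi + lp - 1L
    w <- sub(".*w\\s*=\\s*(\\d+).*", "\\1", lines[lp])
    w <- suppressWarnings(as.integer(w))
    rows <- list()
    j <- lp + 1L
    while (j <= length(lines) && grepl("^[0-9.eE+-]", lines[j])) {
      rows[[length(rows) + 1L]] <-
        as.numeric(strsplit(lines[j], "\\s+")[[1L]])
      j <- j + 1L
    }
    if (!is.na(w) && length(rows) != w)
      stop2("MEME file: motif ", id, " declares w=", w, " but has ",
            length(rows), " rows")
    if (length(rows) == 0L) stop2("MEME file: motif ", id, " has no rows")
    probs <- do.call(rbind, rows)
    if (ncol(probs) != 4L) stop2("MEME file: motif ", id, " rows must have 4 columns")
    sums <- rowSums(probs)
    if (any(abs(sums - 1) > 1e-3))
      stop2("MEME file: motif ", id, " row ", which(abs(sums - 1) > 1e-3)[1L],
            " does not sum to 1 (", format(sums[abs(sums - 1) > 1e-3][1L]), ")")
    pwms[[id]] <- build_pwm(probs, background = background,
                            pseudocount = pseudocount, id = id)
  }
  pwms
}

#' Write a list of PWMs as a MEME minimal file
#' @param pwms List of `pwm` objects.
#' @param path Output path.
#' @param background Optional background frequencies to record in the file.
#' @export
write_meme <- function(pwms, path, background = NULL) {
  out <- c("MEME version 4", "", "ALPHABET= ACGT", "",
           "strands: + -", "")
  if (!is.null(background)) {
    out <- c(out, "Background letter frequencies",
             paste(sprintf("%s %.6f", c("A", "C", "G", "T"), background),
                   collapse = " "), "")
  }
  for (p in pwms) {
    out <- c(out, paste("MOTIF", p$id),
             sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
                     p$width),
             apply(p$probs, 1L, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             "")
  }
  writeLines(out, path)
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' Tab-separated lines: set id, description, member gene ids. Duplicate
#' members within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return A list with one element per set: `list(description=, genes=)`,
#'   named by set id.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop2("GMT line ", i, ": fewer than 3 fields")
    if (f[1L] %in% names(sets)) stop2("GMT: duplicate set id '", f[1L], "'")
    sets[[f[1L]]] <- list(description = f[2L], genes = unique(f[-(1:2)]))
  }
  sets
}

#' Write a GMT gene-set file
#' @param sets A gene-set collection as returned by [read_gmt()].
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  writeLines(vapply(names(sets), function(id)
    paste(c(id, sets[[id]]$description, sets[[id]]$genes), collapse = "\t"),
    character(1)), path)
  invisible(path)
}

edge_table_cols <- c("tf", "target", "pcc", "pcc_p", "motif_p",
                     "motif_start", "strand", "edge_sign")

#' Write a regulatory-network edge table as TSV
#'
#' Columns: tf, target, pcc, pcc_p, motif_p, motif_start, strand, edge_sign;
#' rows sorted by (tf, target); floats with 6 significant digits.
#'
#' @param network Edge data.frame from [assemble_regulatory_network()].
#' @param path Output path.
#' @export
write_edge_table <- function(network, path) {
  if (is.null(network) || nrow(network) == 0L) {
    writeLines(paste(edge_table_cols, collapse = "\t"), path)
    return(invisible(path))
  }
  stopifnot(all(edge_table_cols %in% names(network)))
  net <- network[order(network$tf, network$target), edge_table_cols]
  num <- c("pcc", "pcc_p", "motif_p")
  for (cc in num) net[[cc]] <- formatC(signif(net[[cc]], 6L), format = "g",
                                       digits = 6L)
  lines <- c(paste(edge_table_cols, collapse = "\t"),
             do.call(paste, c(unname(as.list(net)), sep = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' Read an edge table written by [write_edge_table()]
#' @param path Path to the TSV.
#' @return An edge data.frame.
#' @export
read_edge_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(tf = "character",
                                         target = "character",
                                         strand = "character",
                                         edge_sign = "character"))
  if (!identical(names(df), edge_table_cols))
    stop2("edge table: unexpected columns")
  df
}

#' Read a sample design table from TSV
#' @param path TSV with columns sample_id, treatment, timepoint, replicate.
#' @return A design data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  check_design(d)
  d$replicate <- as.integer(d$replicate)
  d
}

#' Write a design table as TSV
#' @param design Design data.frame.
#' @param path Output path.
#' @export
write_design <- function(design, path) {
  check_design(design)
  utils::write.table(design, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
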
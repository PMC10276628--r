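# Readers and writers for the standard plain-text phylogenetic formats:
# FASTA and sequential PHYLIP alignments, newick trees, PAML .dat
# exchangeability matrices.

VALID_AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V",
                    "-", "?", "X")

check_symbols <- function(chars, where) {
  bad <- setdiff(unique(toupper(chars)), VALID_AA_CHARS)
  if (length(bad) > 0L)
    stop(sprintf("parse error (%s): unsupported symbol(s) %s (ambiguity codes are not supported)",
                 where, paste(bad, collapse = " ")), call. = FALSE)
}

#' Read a protein alignment
#'
#' Supports FASTA and sequential PHYLIP.  Gaps and unknowns (`-`, `?`, `X`)
#' are mapped to missing and marginalized in the likelihood; any other
#' non-standard symbol (e.g. ambiguity codes such as `B`) is a parse error.
#'
#' @param path file path.
#' @param format `"fasta"` or `"phylip"`.
#' @return A [bcv_alignment()].
#' @export
read_alignment <- function(path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  lines <- readLines(path)
  if (format == "fasta") {
    hdr <- grep("^>", lines)
    if (length(hdr) == 0L)
      stop("parse error (line 1): no FASTA header found", call. = FALSE)
    taxa <- sub("^>\\s*", "", lines[hdr])
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, character(1))
    seqs <- gsub("\\s", "", seqs)
    lens <- nchar(seqs)
    if (length(unique(lens)) != 1L)
      stop(sprintf("parse error: ragged alignment (sequence lengths %s)",
                   paste(unique(lens), collapse = ", ")), call. = FALSE)
    chars <- matrix(unlist(strsplit(toupper(seqs), "")),
                    nrow = length(taxa), byrow = TRUE)
    check_symbols(chars, "fasta body")
    return(bcv_alignment(taxa, chars))
  }
  # sequential PHYLIP: header "ntaxa nsites", then one record per taxon
  nonblank <- which(nzchar(trimws(lines)))
  if (length(nonblank) == 0L) stop("parse error (line 1): empty file",
                                   call. = FALSE)
  hdr <- strsplit(trimws(lines[nonblank[1L]]), "\\s+")[[1L]]
  if (length(hdr) < 2L || anyNA(suppressWarnings(as.integer(hdr[1:2]))))
    stop(sprintf("parse error (line %d): expected 'ntaxa nsites' header",
                 nonblank[1L]), call. = FALSE)
  ntaxa <- as.integer(hdr[1L]); nsites <- as.integer(hdr[2L])
  body <- nonblank[-1L]
  if (length(body) < ntaxa)
    stop(sprintf("parse error: header announces %d taxa but only %d records found",
                 ntaxa, length(body)), call. = FALSE)
  taxa <- character(ntaxa); seqs <- character(ntaxa)
  for (i in seq_len(ntaxa)) {
    ln <- nonblank[1L + i]
    parts <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    if (length(parts) < 2L)
      stop(sprintf("parse error (line %d): expected 'name sequence'", ln),
           call. = FALSE)
    taxa[i] <- parts[1L]
    seqs[i] <- paste(parts[-1L], collapse = "")
    if (nchar(seqs[i]) != nsites)
      stop(sprintf("parse error (line %d): sequence of %s has %d sites, header says %d",
                   ln, taxa[i], nchar(seqs[i]), nsites), call. = FALSE)
  }
  chars <- matrix(unlist(strsplit(toupper(seqs), "")), nrow = ntaxa,
                  byrow = TRUE)
  check_symbols(chars, "phylip body")
  bcv_alignment(taxa, chars)
}

#' Write a protein alignment
#'
#' @param aln a [bcv_alignment()].
#' @param path file path.
#' @param format `"fasta"` or `"phylip"` (sequential).
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, format = c("fasta", "phylip")) {
  format <- match.arg(format)
  codes <- c(aa_alphabet(), "-")
  idx <- aln$states
  idx[is.na(idx)] <- 21L
  seqs <- apply(idx, 1L, function(r) paste(codes[r], collapse = ""))
  if (format == "fasta") {
    writeLines(as.vector(rbind(paste0(">", aln$taxa), seqs)), path)
  } else {
    writeLines(c(paste(length(aln$taxa), aln$n),
                 paste(aln$taxa, seqs)), path)
  }
  invisible(path)
}

#' Read a newick tree
#'
#' Thin wrapper over `ape::read.tree` that validates branch lengths and,
#' optionally, the leaf set.
#'
#' @param path file path.
#' @param taxa optional character vector the leaf labels must match.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path, taxa = NULL) {
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop("parse error: not a newick tree", call. = FALSE)
  if (is.null(tree$edge.length))
    stop("validation error: tree has no branch lengths", call. = FALSE)
  if (!is.null(taxa) && !setequal(tree$tip.label, taxa))
    stop("validation error: tree leaves do not match the alignment taxa",
         call. = FALSE)
  tree
}

#' Read a PAML-layout amino-acid exchangeability matrix
#'
#' Parses the standard `.dat` layout: 190 lower-triangular exchangeability
#' entries (19 rows) followed by 20 stationary frequencies; both blocks may
#' wrap over lines.  Exchangeabilities and frequencies are renormalized to
#' the simplex.
#'
#' @param path file path.
#' @return List with `rho` (190-vector) and `pi` (20-vector).
#' @export
read_paml_matrix <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines)]
  toks <- suppressWarnings(as.numeric(unlist(strsplit(trimws(lines), "\\s+"))))
  toks <- toks[!is.na(toks)]
  if (length(toks) < 210L)
    stop(sprintf("parse error: expected at least 210 numbers (190 exchangeabilities + 20 frequencies), found %d",
                 length(toks)), call. = FALSE)
  # PAML lower-triangular order is row-wise: row a (2..20), columns 1..a-1,
  # which matches R's lower.tri column-major order only after remapping.
  paml <- toks[1:190]
  freqs <- toks[191:210]
  rho <- numeric(190L)
  S <- matrix(0, 20L, 20L)
  k <- 0L
  for (a in 2:20) for (b in 1:(a - 1L)) {
    k <- k + 1L
    S[a, b] <- paml[k]
  }
  rho <- S[lower.tri(S)]
  if (any(rho < 0) || any(freqs < 0))
    stop("parse error: negative entries in exchangeability file", call. = FALSE)
  list(rho = rho / sum(rho), pi = freqs / sum(freqs))
}

#' Write exchangeabilities and frequencies in PAML layout
#'
#' @param rho 190-vector (lower-triangular, R column-major order).
#' @param pi 20-vector of frequencies.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_paml_matrix <- function(rho, pi, path) {
  S <- matrix(0, 20L, 20L)
  S[lower.tri(S)] <- rho
  rows <- vapply(2:20, function(a)
    paste(format(S[a, 1:(a - 1L)], digits = 8, trim = TRUE), collapse = " "),
    character(1))
  writeLines(c(rows, "", paste(format(pi, digits = 8, trim = TRUE),
                               collapse = " ")), path)
  invisible(path)
}

#' Path to a bundled empirical exchangeability matrix
#'
#' The package ships the published LG, WAG and JTT matrices in PAML layout.
#'
#' @param name `"LG"`, `"WAG"` or `"JTT"`.
#' @return File path inside the installed package.
#' @export
empirical_matrix_path <- function(name = c("LG", "WAG", "JTT")) {
  name <- match.arg(name)
  system.file("extdata", paste0(name, ".dat"), package = "bayescv",
              mustWork = TRUE)
}
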
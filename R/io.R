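#' Read an HMMER3 per-domain hit table (domtblout)
#'
#' Parses the whitespace-separated per-domain tabular output of hmmsearch.
#' When the search was run with Z and domZ forced to 1, the reported
#' E-value columns equal p-values; otherwise supply the Z values used at
#' search time and the columns are divided back down
#' (p_sequence = full-sequence E-value / zSeq, p_domain = i-Evalue / zDom).
#' Envelope coordinates are taken as 1-based inclusive.  Comment ('#') and
#' blank lines are skipped.
#'
#' @param path file path.
#' @param zSeq,zDom the -Z / --domZ values used at search time (default 1).
#' @param censorC drop hits with p_domain above this (default 0.01,
#'   mirroring the usual reporting cutoff); NULL keeps everything.
#' @return a hit table (see \code{\link{validateHits}}); \code{clan_id} is
#'   NA and can be filled from a clan map.
#' @export
readDomtblout <- function(path, zSeq = 1, zDom = 1, censorC = 0.01) {
  stopifnot(zSeq > 0, zDom > 0)
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (!length(lines))
    return(data.frame(protein_id = character(0), family_id = character(0),
                      clan_id = character(0), env_start = integer(0),
                      env_end = integer(0), bitscore = numeric(0),
                      p_domain = numeric(0), p_sequence = numeric(0)))
  fields <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(fields, length, integer(1)) < 22L)
  if (length(bad))
    stop("malformed domtblout line ", bad[1], ": expected >= 22 columns")
  getNum <- function(k, what) {
    v <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), k)))
    if (anyNA(v))
      stop("malformed domtblout line ", which(is.na(v))[1],
           ": non-numeric ", what)
    v
  }
  hits <- data.frame(
    protein_id = vapply(fields, `[[`, character(1), 1L),
    family_id  = vapply(fields, `[[`, character(1), 4L),
    clan_id    = NA_character_,
    env_start  = as.integer(getNum(20L, "env from")),
    env_end    = as.integer(getNum(21L, "env to")),
    bitscore   = getNum(14L, "domain score"),
    p_domain   = getNum(13L, "i-Evalue") / zDom,
    p_sequence = getNum(7L, "full-sequence E-value") / zSeq)
  if (!is.null(censorC))
    hits <- hits[hits$p_domain <= censorC, , drop = FALSE]
  rownames(hits) <- NULL
  validateHits(hits)
  hits
}

#' Write / read an annotated hit table as TSV
#'
#' Tab-separated with a header; numeric columns are serialized at 12
#' significant digits, \code{removed_overlap} as 0/1, so that
#' write-then-read round-trips losslessly at that precision.
#'
#' @param hits annotated hit table (columns protein_id, family_id,
#'   clan_id, env_start, env_end, bitscore, p_domain, p_sequence, evalue,
#'   qvalue, lfdr, removed_overlap).
#' @param path output file.
#' @export
writeAnnotated <- function(hits, path) {
  cols <- c("protein_id", "family_id", "clan_id", "env_start", "env_end",
            "bitscore", "p_domain", "p_sequence", "evalue", "qvalue",
            "lfdr", "removed_overlap")
  miss <- setdiff(cols, names(hits))
  if (length(miss))
    stop("annotated table is missing columns: ", paste(miss, collapse = ", "))
  out <- hits[, cols, drop = FALSE]
  out$removed_overlap <- as.integer(out$removed_overlap)
  for (k in c("bitscore", "p_domain", "p_sequence", "evalue", "qvalue",
              "lfdr"))
    out[[k]] <- sprintf("%.12g", out[[k]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

#' @rdname writeAnnotated
#' @return \code{readAnnotated} returns the annotated hit table with
#'   native column types.
#' @export
readAnnotated <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c(protein_id = "character",
                                        family_id = "character",
                                        clan_id = "character"),
                         na.strings = "NA")
  h$removed_overlap <- as.logical(h$removed_overlap)
  h
}

#' Read two-column family tables (clan map, nesting list, context pairs)
#'
#' All three auxiliary inputs are headered two-column TSV files.  The clan
#' map (family_id, clan_id) is returned as a named character vector; pair
#' lists (family_a, family_b) as \code{\link{familyPairs}} tables.
#'
#' @param path TSV file path.
#' @return named character vector (clan map) or familyPairs data.frame.
#' @export
readClanMap <- function(path) {
  t <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  setNames(t[[2]], t[[1]])
}

#' @rdname readClanMap
#' @export
readFamilyPairs <- function(path) {
  t <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = "character")
  familyPairs(t[[1]], t[[2]])
}

#' @rdname readClanMap
#' @param clanMap named character vector (family_id -> clan_id).
#' @export
writeClanMap <- function(clanMap, path) {
  utils::write.table(
    data.frame(family_id = names(clanMap), clan_id = unname(clanMap)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname readClanMap
#' @param pairs a \code{\link{familyPairs}} table.
#' @export
writeFamilyPairs <- function(pairs, path) {
  utils::write.table(pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' FASTA convenience wrappers
#'
#' Thin wrappers over Biostrings for the protein FASTA files the decoy
#' workflow touches.
#'
#' @param path FASTA file.
#' @return \code{readProteinFasta}: an AAStringSet.
#' @export
readProteinFasta <- function(path) Biostrings::readAAStringSet(path)

#' @rdname readProteinFasta
#' @param records an AAStringSet (or named character vector).
#' @export
writeProteinFasta <- function(records, path)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(records), path)
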
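#' Read and write FASTA
#'
#' `read_fasta()` returns the records of a (possibly gzipped) FASTA file in
#' file order, sequences uppercased. The record id is the header token before
#' the first whitespace; the remainder is kept as the description. An empty
#' file yields an empty list; a record with an empty sequence is a format
#' error.
#'
#' @param path FASTA file.
#' @return List of records, each `list(id =, seq =, desc =)`; names are ids.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0) return(list())
  if (any(Biostrings::width(x) == 0))
    stop("FASTA format error: empty sequence under header '",
         names(x)[Biostrings::width(x) == 0][1], "'")
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(x))
  out <- mapply(function(i, s, d) list(id = i, seq = s, desc = d),
                ids, seqs, desc, SIMPLIFY = FALSE)
  names(out) <- ids
  out
}

#' @rdname read_fasta
#' @param records named character vector of sequences, or the list form
#'   returned by `read_fasta()`.
#' @export
write_fasta <- function(records, path) {
  if (is.list(records) && length(records) && is.list(records[[1]]))
    records <- setNames(vapply(records, `[[`, "", "seq"),
                        vapply(records, `[[`, "", "id"))
  writeLines(as.vector(rbind(paste0(">", names(records)),
                             as.character(records))), path)
  invisible(path)
}

#' Construct a genome record
#'
#' One genome of the collection: its contigs, phenotype group label, whether
#' it is a cultured isolate or a metagenome-assembled genome (MAG), and its
#' CheckM-style completeness/contamination estimates.
#'
#' @param genome_id unique id.
#' @param contigs named character vector of uppercase DNA contigs.
#' @param group `"PTB"`, `"FTB"` or `"UNKNOWN"` (preterm/full-term birth).
#' @param source `"ISOLATE"` or `"MAG"`.
#' @param completeness,contamination percentages; completeness in \[0, 100\],
#'   contamination non-negative.
#' @return A `genome_record`.
#' @export
genome_record <- function(genome_id, contigs, group = "UNKNOWN",
                          source = "ISOLATE", completeness = 100,
                          contamination = 0) {
  stopifnot(is.character(genome_id), length(genome_id) == 1, nzchar(genome_id),
            is.character(contigs), length(contigs) >= 1,
            !is.null(names(contigs)), all(nzchar(contigs)),
            completeness >= 0, completeness <= 100, contamination >= 0)
  group <- match.arg(group, c("PTB", "FTB", "UNKNOWN"))
  source <- match.arg(source, c("ISOLATE", "MAG"))
  contigs[] <- toupper(contigs)
  if (any(grepl("[^ACGTN]", contigs)))
    stop("contigs may contain only A/C/G/T/N")
  structure(list(genome_id = genome_id, contigs = contigs, group = group,
                 source = source, completeness = completeness,
                 contamination = contamination),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("genome %s [%s, %s]: %d contig(s), %.0f bp, completeness %.1f%%, contamination %.1f%%\n",
              x$genome_id, x$group, x$source, length(x$contigs),
              sum(nchar(x$contigs)), x$completeness, x$contamination))
  invisible(x)
}

#' Extract CDS genes from a GFF3 annotation
#'
#' Reads CDS features whose seqid matches a contig of `genome`, extracts the
#' nucleotide sequence (1-based inclusive coordinates; minus-strand features
#' are reverse-complemented), and translates with the bacterial genetic code
#' (transl_table 11). The terminal stop is removed from the protein; CDS whose
#' length is not a multiple of 3 (frame-broken MAG fragments) are skipped with
#' a warning; CDS with internal stops are kept and flagged.
#'
#' @param gff_path GFF3 file with CDS features.
#' @param genome a [genome_record()].
#' @return A data.frame of genes: `gene_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `strand`, `nt_seq`, `aa_seq`, `internal_stop`.
#' @export
read_gff_genes <- function(gff_path, genome) {
  stopifnot(file.exists(gff_path), inherits(genome, "genome_record"))
  gr <- rtracklayer::import(gff_path)
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0) return(empty_gene_table())
  seqid <- as.character(GenomicRanges::seqnames(gr))
  unknown <- setdiff(unique(seqid), names(genome$contigs))
  if (length(unknown))
    stop("GFF seqid(s) not among genome contigs: ",
         paste(unknown, collapse = ", "))
  starts <- GenomicRanges::start(gr)
  ends <- GenomicRanges::end(gr)
  strands <- as.character(GenomicRanges::strand(gr))
  strands[strands == "*"] <- "+"
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else rep(NA_character_, length(gr))
  ids[is.na(ids) | !nzchar(ids)] <-
    paste0(genome$genome_id, "_cds", which(is.na(ids) | !nzchar(ids)))
  clen <- nchar(genome$contigs)[seqid]
  if (any(ends > clen) || any(starts < 1))
    stop("CDS coordinates exceed contig length (", gff_path, ")")
  keep <- (ends - starts + 1) %% 3 == 0
  if (any(!keep))
    warning(sum(!keep), " CDS with length not divisible by 3 skipped (",
            paste(head(ids[!keep], 5), collapse = ","), ")")
  if (!any(keep)) return(empty_gene_table())
  nt <- substring(genome$contigs[seqid[keep]], starts[keep], ends[keep])
  minus <- strands[keep] == "-"
  if (any(minus)) nt[minus] <- revcomp(nt[minus])
  aa <- translate_cds(nt)
  data.frame(gene_id = ids[keep], genome_id = genome$genome_id,
             contig_id = seqid[keep], start = starts[keep], end = ends[keep],
             strand = strands[keep], nt_seq = unname(nt),
             aa_seq = unname(aa$protein),
             internal_stop = unname(aa$internal_stop),
             stringsAsFactors = FALSE)
}

empty_gene_table <- function() {
  data.frame(gene_id = character(0), genome_id = character(0),
             contig_id = character(0), start = integer(0), end = integer(0),
             strand = character(0), nt_seq = character(0),
             aa_seq = character(0), internal_stop = logical(0),
             stringsAsFactors = FALSE)
}

#' Translate complete CDS sequences (bacterial code, table 11)
#'
#' Ambiguous codons (containing N) translate to `X`; the terminal stop, if
#' present, is removed; internal stops are kept in the protein and flagged.
#'
#' @param nt character vector of CDS nucleotide sequences (length multiple of 3).
#' @return list with `protein` and logical `internal_stop`.
#' @export
translate_cds <- function(nt) {
  stopifnot(all(nchar(nt) %% 3 == 0))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(nt),
    genetic.code = Biostrings::getGeneticCode("11"),
    no.init.codon = TRUE, # plain per-codon lookup, no initiator-to-M rule
    if.fuzzy.codon = "X"))
  aa <- sub("\\*$", "", aa)
  list(protein = aa, internal_stop = grepl("*", aa, fixed = TRUE))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Read or write a gene presence/absence matrix (Rtab-style TSV)
#'
#' Tab-separated, first column `Gene` holding family ids, one column per
#' genome, cells 0/1. `read_presence_absence(write_presence_absence(M)) == M`.
#'
#' @param m binary matrix, rownames = family ids, colnames = genome ids.
#' @param path file path.
#' @export
write_presence_absence <- function(m, path) {
  stopifnot(is.matrix(m), all(m %in% c(0, 1)))
  df <- data.frame(Gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_presence_absence
#' @export
read_presence_absence <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2 || names(df)[1] != "Gene")
    stop("presence/absence format error: first column must be 'Gene'")
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!all(m %in% c(0, 1)))
    stop("presence/absence format error: non-binary cell")
  storage.mode(m) <- "integer"
  rownames(m) <- df$Gene
  m
}

#' Read or write the genome metadata table
#'
#' One row per genome: `genome_id`, `group` (PTB/FTB/UNKNOWN), `source`
#' (ISOLATE/MAG), `completeness`, `contamination`, plus any extra columns
#' (e.g. gestation weeks, CST) passed through untouched.
#'
#' @param metadata data.frame with at least the columns above.
#' @param path TSV file.
#' @export
write_metadata <- function(metadata, path) {
  write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metadata
#' @export
read_metadata <- function(path) {
  md <- read.delim(path, stringsAsFactors = FALSE)
  validate_metadata(md)
  md
}

validate_metadata <- function(md) {
  req <- c("genome_id", "group")
  if (!all(req %in% names(md)))
    stop("metadata error: missing column(s) ",
         paste(setdiff(req, names(md)), collapse = ", "))
  if (anyDuplicated(md$genome_id))
    stop("metadata error: duplicated genome_id")
  if (!all(md$group %in% c("PTB", "FTB", "UNKNOWN")))
    stop("metadata error: group must be PTB, FTB or UNKNOWN")
  invisible(md)
}

#' Write a phylogenetic tree to Newick
#'
#' Branch lengths are preserved at full precision; internal-node support
#' values (if present in `node.label`) are serialized as internal node labels.
#'
#' @param tree an `ape::phylo` object.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
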
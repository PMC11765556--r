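# Core sequence-set container and readers/writers for the external formats
# the pipeline touches (FASTA/FASTQ, MEME minimal motifs, narrowPeak, GFF3).

#' Ligand library: a set of equal-length SELEX reads
#'
#' The unit flowing through all SELEX stages: uppercase ACGT reads of equal
#' length, a cycle index (0 = unselected input library), a library-level
#' methylation flag (in a Methyl-SELEX library every cytosine is 5mC, on both
#' strands, so methylation is a property of the library rather than of
#' individual bases), and the coordinates of the randomised region within
#' each read.
#'
#' @param reads character vector of ACGT reads, all the same length.
#' @param cycle integer selection cycle (>= 0); 0 is the input library.
#' @param methylated logical; TRUE for a fully 5mC-methylated library.
#' @param random_region integer pair `c(start, length)` (1-based start) giving
#'   the randomised region within each read; defaults to the whole read.
#' @param label free-text label.
#' @return an object of class `LigandLibrary`.
#' @export
LigandLibrary <- function(reads, cycle = 0L, methylated = FALSE,
                          random_region = NULL, label = "") {
  reads <- toupper(as.character(reads))
  if (length(reads) == 0L) stop("a LigandLibrary needs at least one read")
  L <- nchar(reads[1])
  if (any(nchar(reads) != L)) {
    bad <- which(nchar(reads) != L)[1]
    stop(sprintf("unequal read lengths: read %d has %d nt, expected %d",
                 bad, nchar(reads[bad]), L))
  }
  if (any(grepl("[^ACGT]", reads))) {
    bad <- which(grepl("[^ACGT]", reads))[1]
    stop(sprintf("read %d contains characters outside ACGT", bad))
  }
  if (is.null(random_region)) random_region <- c(1L, L)
  random_region <- as.integer(random_region)
  if (length(random_region) != 2L || random_region[1] < 1L ||
      random_region[2] < 1L || random_region[1] + random_region[2] - 1L > L)
    stop("random_region must lie within read bounds")
  cycle <- as.integer(cycle)
  if (is.na(cycle) || cycle < 0L) stop("cycle must be a non-negative integer")
  structure(list(reads = reads, cycle = cycle,
                 methylated = isTRUE(methylated),
                 random_region = c(start = random_region[1],
                                   length = random_region[2]),
                 label = as.character(label)),
            class = "LigandLibrary")
}

#' @export
print.LigandLibrary <- function(x, ...) {
  cat(sprintf("LigandLibrary: %d reads x %d nt | cycle %d | %s%s\n",
              length(x$reads), nchar(x$reads[1]), x$cycle,
              if (x$methylated) "methylated (5mC)" else "unmethylated",
              if (nzchar(x$label)) paste0(" | ", x$label) else ""))
  cat(sprintf("  random region: start %d, length %d\n",
              x$random_region["start"], x$random_region["length"]))
  invisible(x)
}

# randomised-region substrings of a library's reads
region_reads <- function(library) {
  s <- library$random_region["start"]
  substr(library$reads, s, s + library$random_region["length"] - 1L)
}

#' Read a SELEX library from FASTA/FASTQ
#'
#' Reads are uppercased; records containing characters outside ACGTN are
#' rejected; records containing N are dropped (with a message), because the
#' downstream k-mer and motif statistics assume a complete alphabet; all
#' surviving reads must have equal length.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @param random_region optional `c(start, length)` of the randomised region.
#' @param methylated logical library-level 5mC flag.
#' @param cycle integer selection cycle.
#' @param label free-text label; defaults to the file name.
#' @return a [LigandLibrary].
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           random_region = NULL, methylated = FALSE,
                           cycle = 0L, label = basename(path)) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto")
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE))
      "fastq" else "fasta"
  x <- Biostrings::readDNAStringSet(path, format = format)
  if (length(x) == 0L) stop("no records in ", path)
  s <- toupper(as.character(x))
  nm <- names(x)
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop(sprintf("record '%s' contains characters outside ACGTN",
                 nm[which(bad)[1]]))
  hasN <- grepl("N", s, fixed = TRUE)
  if (any(hasN)) {
    message(sum(hasN), " record(s) containing N dropped")
    s <- s[!hasN]; nm <- nm[!hasN]
  }
  if (length(s) == 0L) stop("all records dropped (every read contained N)")
  L <- nchar(s[1])
  if (any(nchar(s) != L)) {
    i <- which(nchar(s) != L)[1]
    stop(sprintf("unequal read lengths: record '%s' has %d nt, expected %d",
                 nm[i], nchar(s[i]), L))
  }
  LigandLibrary(s, cycle = cycle, methylated = methylated,
                random_region = random_region, label = label)
}

#' Write a ligand library to FASTA or FASTQ
#'
#' @param library a [LigandLibrary].
#' @param path output file.
#' @param format `"fasta"` or `"fastq"` (constant `I` qualities).
#' @return `path`, invisibly.
#' @export
write_sequences <- function(library, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  x <- Biostrings::DNAStringSet(library$reads)
  names(x) <- sprintf("read_%d", seq_along(x))
  if (format == "fastq") {
    q <- Biostrings::BStringSet(rep(strrep("I", nchar(library$reads[1])),
                                    length(x)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  } else {
    Biostrings::writeXStringSet(x, path, format = "fasta")
  }
  invisible(path)
}

#' Write motifs in MEME minimal format
#'
#' Emits a MEME version 4 minimal motif file (uniform background, both
#' strands) readable by standard MEME-suite tools. Probabilities are written
#' with six decimals, so a write/read round trip preserves matrices to 1e-6.
#'
#' @param models a [pwm_model] or list of them.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_motif_meme <- function(models, path) {
  if (inherits(models, "PWMModel")) models <- list(models)
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "", "strands: + -", "",
               "Background letter frequencies",
               "A 0.25 C 0.25 G 0.25 T 0.25", ""), con)
  for (m in models) {
    M <- m$matrix
    if (any(abs(colSums(M) - 1) > 1e-9))
      stop("un-normalized PWM column in motif '", m$name, "'")
    nsites <- if (is.finite(m$nsites)) m$nsites else 20
    writeLines(sprintf("MOTIF %s %s", m$name,
                       if (nzchar(m$seed)) m$seed else m$name), con)
    writeLines(sprintf(
      "letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
      ncol(M), nsites), con)
    for (j in seq_len(ncol(M)))
      writeLines(sprintf(" %.6f %.6f %.6f %.6f",
                         M[1, j], M[2, j], M[3, j], M[4, j]), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal motif file
#'
#' @param path MEME file written by [write_motif_meme()] or compatible.
#' @return list of [pwm_model] objects (possibly empty).
#' @export
read_motif_meme <- function(path) {
  lines <- readLines(path)
  starts <- grep("^MOTIF\\b", lines)
  models <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    hdr <- strsplit(trimws(lines[starts[i]]), "\\s+")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else ""
    seed <- if (length(hdr) >= 3) hdr[3] else ""
    j <- starts[i] + 1L
    while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
      j <- j + 1L
    if (j > length(lines)) stop("malformed MEME file: missing matrix for ", name)
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", lines[j]))
    rows <- lines[(j + 1L):(j + w)]
    M <- t(vapply(rows, function(r)
      as.numeric(strsplit(trimws(r), "\\s+")[[1]][1:4]), numeric(4)))
    M <- t(M)  # back to 4 x w (rows A,C,G,T)
    M <- sweep(M, 2, colSums(M), "/")
    models[[i]] <- pwm_model(M, seed = seed, name = name)
  }
  models
}

#' Read a MACS-style narrowPeak file as a peak set
#'
#' narrowPeak is BED6+4; intervals are returned as a `GRanges` (1-based,
#' closed, as usual for Bioconductor; the underlying file is 0-based
#' half-open) with the `signalValue` column as peak intensity. Ranking
#' helpers order peaks by descending `signalValue`, ties broken by
#' (chromosome, start).
#'
#' @param path narrowPeak file.
#' @return `GRanges` with metadata columns `name`, `score`, `signalValue`,
#'   `pValue`, `qValue`, `peak`.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "BED",
                            extraCols = c(signalValue = "numeric",
                                          pValue = "numeric",
                                          qValue = "numeric",
                                          peak = "integer"))
  if (any(GenomicRanges::width(gr) < 1L))
    stop("invalid narrowPeak interval: start >= end")
  sv <- gr$signalValue
  if (!is.numeric(sv) || any(is.na(sv)))
    stop("non-numeric signalValue in ", path)
  if (any(!is.finite(sv)) || any(sv < 0))
    stop("signalValue must be finite and >= 0")
  gr
}

#' Write a peak set as narrowPeak
#'
#' @param peaks `GRanges` with a `signalValue` column (other narrowPeak
#'   columns are filled with placeholders when absent).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  mc <- S4Vectors::mcols(peaks)
  grab <- function(col, default) if (col %in% names(mc)) mc[[col]] else default
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(peaks)),
    start = GenomicRanges::start(peaks) - 1L,
    end = GenomicRanges::end(peaks),
    name = grab("name", sprintf("peak_%d", seq_along(peaks))),
    score = grab("score", 0L),
    strand = ".",
    signalValue = grab("signalValue", 0),
    pValue = grab("pValue", -1),
    qValue = grab("qValue", -1),
    peak = grab("peak", -1L))
  df$score[is.na(df$score)] <- 0L
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Rank order of a peak set
#'
#' The ordering used wherever "top peaks" are taken: descending
#' `signalValue`, ties broken by chromosome then start.
#'
#' @param peaks peak `GRanges` with a `signalValue` column.
#' @return integer permutation ranking the peaks.
#' @export
peak_rank_order <- function(peaks) {
  order(-peaks$signalValue,
        as.character(GenomicRanges::seqnames(peaks)),
        GenomicRanges::start(peaks))
}

#' Genome plus TSS annotation
#'
#' Container pairing named genome sequences with a strand-aware TSS table.
#'
#' @param sequences a `DNAStringSet` (or named character vector) of
#'   chromosome sequences.
#' @param tss data.frame with columns `chrom`, `pos` (0-based TSS position),
#'   `strand` (`+`/`-`) and `gene_id`.
#' @return an object of class `GenomeAnnotation`.
#' @export
GenomeAnnotation <- function(sequences, tss) {
  if (is.character(sequences)) sequences <- Biostrings::DNAStringSet(sequences)
  if (is.null(names(sequences)) || any(!nzchar(names(sequences))))
    stop("genome sequences must be named")
  need <- c("chrom", "pos", "strand", "gene_id")
  if (!all(need %in% names(tss)))
    stop("tss table needs columns: ", paste(need, collapse = ", "))
  tss <- as.data.frame(tss)[need]
  if (!all(tss$chrom %in% names(sequences)))
    stop("TSS chromosome absent from genome sequences: ",
         setdiff(tss$chrom, names(sequences))[1])
  if (!all(tss$strand %in% c("+", "-")))
    stop("TSS strand must be '+' or '-'")
  lens <- setNames(Biostrings::width(sequences), names(sequences))
  if (any(tss$pos < 0 | tss$pos >= lens[tss$chrom]))
    stop("TSS position outside chromosome bounds")
  structure(list(sequences = sequences, tss = tss), class = "GenomeAnnotation")
}

#' @export
print.GenomeAnnotation <- function(x, ...) {
  cat(sprintf("GenomeAnnotation: %d sequence(s), %d TSS(s)\n",
              length(x$sequences), nrow(x$tss)))
  invisible(x)
}

#' Read a genome (FASTA) and its gene annotation (GFF3)
#'
#' TSSs are the strand-aware 5' ends of `feature_type` records (0-based).
#'
#' @param fasta_path genome FASTA.
#' @param gff_path GFF3 annotation.
#' @param feature_type feature type to take genes from (default `"gene"`).
#' @return a [GenomeAnnotation].
#' @export
read_genome_annotation <- function(fasta_path, gff_path,
                                   feature_type = "gene") {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  gff <- rtracklayer::import(gff_path, format = "gff3")
  genes <- gff[gff$type == feature_type]
  if (length(genes) == 0L)
    stop("no '", feature_type, "' features in ", gff_path)
  ids <- genes$ID
  if (is.null(ids) || any(is.na(ids))) ids <- genes$Name
  if (is.null(ids) || any(is.na(ids))) ids <- sprintf("gene_%d", seq_along(genes))
  strand <- as.character(GenomicRanges::strand(genes))
  if (any(strand == "*")) stop("gene strand must be '+' or '-'")
  pos <- ifelse(strand == "+",
                GenomicRanges::start(genes) - 1L,
                GenomicRanges::end(genes) - 1L)
  GenomeAnnotation(seqs,
                   data.frame(chrom = as.character(GenomicRanges::seqnames(genes)),
                              pos = pos, strand = strand, gene_id = ids))
}
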
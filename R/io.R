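# Format readers/writers. Sequences live in memory as named character
# vectors; coordinates are 0-based half-open internally and converted to the
# 1-based conventions of SAM/VCF/GFF3/AGP only at the file boundary.

#' Read / write FASTA
#'
#' @param path file path.
#' @param x named character vector of sequences.
#' @param width line wrap width (default 60 columns).
#' @return `read_fasta` returns a named character vector.
#' @export
read_fasta <- function(path) {
  s <- Biostrings::readDNAStringSet(path)
  out <- as.character(s)
  names(out) <- sub("\\s.*$", "", names(s))
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(x, path, width = 60) {
  s <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(s, path, width = width)
  invisible(path)
}

#' Read / write FASTQ (Phred+33)
#'
#' @param path file path.
#' @param seq named character vector of read sequences.
#' @param qual character vector of quality strings (same lengths as `seq`).
#' @return `read_fastq` returns list(seq, qual), both named character vectors.
#' @export
read_fastq <- function(path) {
  s <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  nm <- sub("\\s.*$", "", names(s))
  list(seq = setNames(as.character(s), nm),
       qual = setNames(as.character(Biostrings::quality(s)), nm))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seq, qual, path) {
  stopifnot(length(seq) == length(qual), !is.null(names(seq)))
  # metadata-column drop notices are irrelevant for plain read sets
  suppressWarnings({
    s <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seq),
      Biostrings::PhredQuality(qual))
    Biostrings::writeQualityScaledXStringSet(s, path)
  })
  invisible(path)
}

# --- SAM subset ------------------------------------------------------------
# Mandatory fields only; CIGAR ops M/I/D/S/H/=/X; in-memory pos is 0-based.

#' Read / write a SAM subset
#'
#' Supports the mandatory 11 columns with CIGAR ops M/I/D/S/H/=/X. In-memory
#' `pos` and `pnext` are 0-based (half-open); the file is standard 1-based
#' SAM. Optional tags are dropped on read.
#'
#' @param path file path.
#' @param records data.frame with columns qname, flag, rname, pos, mapq,
#'   cigar, rnext, pnext, tlen, seq, qual.
#' @param ref_lengths named numeric vector for the @SQ header lines.
#' @return `read_sam` returns the records data.frame.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(empty_df(data.frame(qname = "", flag = 0L, rname = "", pos = 0,
                               mapq = 0L, cigar = "", rnext = "", pnext = 0,
                               tlen = 0, seq = "", qual = "")))
  f <- strsplit(lines, "\t", fixed = TRUE)
  bad <- vapply(f, length, integer(1)) < 11
  if (any(bad)) stop("malformed SAM record at line(s): ",
                     paste(utils::head(which(bad), 3), collapse = ", "))
  g <- function(i) vapply(f, `[[`, character(1), i)
  data.frame(qname = g(1), flag = as.integer(g(2)), rname = g(3),
             pos = as.numeric(g(4)) - 1, mapq = as.integer(g(5)),
             cigar = g(6), rnext = g(7), pnext = as.numeric(g(8)) - 1,
             tlen = as.numeric(g(9)), seq = g(10), qual = g(11))
}

#' @rdname read_sam
#' @export
write_sam <- function(records, ref_lengths, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(ref_lengths),
                   as.integer(ref_lengths)))
  body <- if (nrow(records)) {
    sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s",
            records$qname, records$flag, records$rname,
            as.integer(records$pos + 1), records$mapq, records$cigar,
            records$rnext, as.integer(records$pnext + 1),
            as.integer(records$tlen), records$seq, records$qual)
  } else character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}

# --- GFF3 ------------------------------------------------------------------

#' Write gene models as GFF3
#'
#' @param models gene-model data.frame (see [simulate_genes()]): columns
#'   gene_id, transcript_id, chrom, strand, feature (gene/mRNA/exon/CDS),
#'   start, end (0-based half-open), phase.
#' @param path file path.
#' @export
write_gff3 <- function(models, path) {
  lines <- "##gff-version 3"
  if (nrow(models)) {
    attr_col <- ifelse(models$feature == "gene",
                       sprintf("ID=%s", models$gene_id),
                ifelse(models$feature == "mRNA",
                       sprintf("ID=%s;Parent=%s", models$transcript_id,
                               models$gene_id),
                       sprintf("Parent=%s", models$transcript_id)))
    lines <- c(lines,
               sprintf("%s\tpseudoref\t%s\t%d\t%d\t.\t%s\t%s\t%s",
                       models$chrom, models$feature,
                       as.integer(models$start + 1), as.integer(models$end),
                       models$strand,
                       ifelse(is.na(models$phase), ".",
                              as.character(models$phase)),
                       attr_col))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read GFF3 gene models
#'
#' Uses rtracklayer when available; falls back to a minimal parser of the
#' nine mandatory columns. Returns the same 0-based table [write_gff3()]
#' consumes.
#'
#' @param path file path.
#' @return gene-model data.frame.
#' @export
read_gff3 <- function(path) {
  proto <- data.frame(gene_id = "", transcript_id = "", chrom = "",
                      strand = "", feature = "", start = 0, end = 0,
                      phase = NA_integer_)
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    g <- rtracklayer::import(path, format = "gff3")
    if (!length(g)) return(empty_df(proto))
    md <- as.data.frame(g)
    gene_id <- as.character(md$ID)
    parent <- vapply(as.list(md$Parent), function(p)
      if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
    feat <- as.character(md$type)
    tid <- ifelse(feat == "mRNA", gene_id, parent)
    gid <- ifelse(feat == "gene", gene_id, parent)
    # exons/CDS carry their transcript as Parent; look up its gene
    t2g <- setNames(gid[feat == "mRNA"], tid[feat == "mRNA"])
    gid[!feat %in% c("gene", "mRNA")] <- t2g[tid[!feat %in% c("gene", "mRNA")]]
    out <- data.frame(gene_id = gid, transcript_id = tid,
                      chrom = as.character(md$seqnames),
                      strand = as.character(md$strand), feature = feat,
                      start = md$start - 1, end = md$end,
                      phase = suppressWarnings(as.integer(as.character(md$phase))))
    return(out)
  }
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (!length(lines)) return(empty_df(proto))
  f <- strsplit(lines, "\t", fixed = TRUE)
  g <- function(i) vapply(f, `[[`, character(1), i)
  attrs <- g(9)
  get_attr <- function(key) {
    m <- regmatches(attrs, regexpr(paste0(key, "=[^;]+"), attrs))
    out <- rep(NA_character_, length(attrs))
    out[grepl(paste0(key, "="), attrs)] <- sub(paste0(key, "="), "", m)
    out
  }
  feat <- g(3)
  id <- get_attr("ID"); parent <- get_attr("Parent")
  tid <- ifelse(feat == "mRNA", id, parent)
  gid <- ifelse(feat == "gene", id, parent)
  t2g <- setNames(gid[feat == "mRNA"], tid[feat == "mRNA"])
  gid[!feat %in% c("gene", "mRNA")] <- t2g[tid[!feat %in% c("gene", "mRNA")]]
  data.frame(gene_id = gid, transcript_id = tid, chrom = g(1),
             strand = g(7), feature = feat,
             start = as.numeric(g(4)) - 1, end = as.numeric(g(5)),
             phase = suppressWarnings(as.integer(g(8))))
}

# --- VCF -------------------------------------------------------------------

#' Write SNP and large-indel calls as VCF 4.2
#'
#' SNPs are plain records; large indels are symbolic `<DEL>`/`<INS>` records
#' with END and SVLEN INFO fields. Positions convert from internal 0-based to
#' 1-based VCF.
#'
#' @param snps SNP table from [call_snps()] (may be NULL).
#' @param indels large-indel table from the classifiers (may be NULL).
#' @param ref reference genome (named character) for header lengths and
#'   anchor bases.
#' @param path file path.
#' @export
write_vcf <- function(snps, indels, ref, path) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(ref),
                   as.integer(nchar(ref))),
           "##ALT=<ID=DEL,Description=\"Deletion\">",
           "##ALT=<ID=INS,Description=\"Insertion\">",
           "##INFO=<ID=END,Number=1,Type=Integer,Description=\"SV end\">",
           "##INFO=<ID=SVLEN,Number=1,Type=Integer,Description=\"SV length\">",
           "##INFO=<ID=SVTYPE,Number=1,Type=String,Description=\"SV type\">",
           "##INFO=<ID=VALIDATED,Number=0,Type=Flag,Description=\"Breakpoints supported by >=5 spanning reads and a straddling pair\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  rows <- character(0)
  if (!is.null(snps) && nrow(snps)) {
    rows <- c(rows, sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.", snps$chrom,
                            as.integer(snps$r_pos + 1), snps$ref_base,
                            snps$alt_base))
  }
  if (!is.null(indels) && nrow(indels)) {
    anchor <- substr(ref[indels$chrom], indels$r_pos, indels$r_pos)
    anchor[anchor == "" | is.na(anchor)] <- "N"
    val <- if ("validated" %in% names(indels))
      ifelse(!is.na(indels$validated) & indels$validated, ";VALIDATED", "")
    else ""
    svlen <- ifelse(indels$type == "DEL", -indels$size, indels$size)
    endpos <- ifelse(indels$type == "DEL", indels$r_pos + indels$size,
                     indels$r_pos)
    rows <- c(rows, sprintf("%s\t%d\t.\t%s\t<%s>\t.\tPASS\tSVTYPE=%s;END=%d;SVLEN=%d%s",
                            indels$chrom, as.integer(indels$r_pos),
                            anchor, indels$type, indels$type,
                            as.integer(endpos + 1), as.integer(svlen), val))
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

# --- AGP -------------------------------------------------------------------

#' Write / read AGP v2.0 and rebuild FASTA from it
#'
#' `assemble_from_agp(agp, contigs)` reconstructs the object sequences
#' byte-identically to the pseudomolecule FASTA emitted alongside the AGP.
#'
#' @param agp AGP data.frame as produced by [build_pseudomolecules()]:
#'   columns object, object_beg, object_end (1-based inclusive), part_number,
#'   component_type (W/N/U), and the component or gap columns.
#' @param path file path.
#' @param contigs named character vector of component sequences.
#' @return `read_agp` returns the AGP data.frame; `assemble_from_agp` a named
#'   character vector of object sequences.
#' @export
write_agp <- function(agp, path) {
  lines <- c("##agp-version\t2.0")
  if (nrow(agp)) {
    lines <- c(lines, vapply(seq_len(nrow(agp)), function(i) {
      r <- agp[i, ]
      if (r$component_type == "W")
        sprintf("%s\t%d\t%d\t%d\tW\t%s\t%d\t%d\t%s", r$object,
                as.integer(r$object_beg), as.integer(r$object_end),
                as.integer(r$part_number), r$component_id,
                as.integer(r$component_beg), as.integer(r$component_end),
                r$orientation)
      else
        sprintf("%s\t%d\t%d\t%d\t%s\t%d\tscaffold\tyes\talign_genus",
                r$object, as.integer(r$object_beg), as.integer(r$object_end),
                as.integer(r$part_number), r$component_type,
                as.integer(r$gap_length))
    }, character(1)))
  }
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_agp
#' @export
read_agp <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  proto <- data.frame(object = "", object_beg = 0, object_end = 0,
                      part_number = 0L, component_type = "",
                      component_id = NA_character_, component_beg = NA_real_,
                      component_end = NA_real_, orientation = NA_character_,
                      gap_length = NA_real_)
  if (!length(lines)) return(empty_df(proto))
  f <- strsplit(lines, "\t", fixed = TRUE)
  do.call(rbind, lapply(f, function(x) {
    r <- proto
    r[1, c("object", "object_beg", "object_end", "part_number",
           "component_type")] <-
      list(x[1], as.numeric(x[2]), as.numeric(x[3]), as.integer(x[4]), x[5])
    if (x[5] == "W") {
      r$component_id <- x[6]; r$component_beg <- as.numeric(x[7])
      r$component_end <- as.numeric(x[8]); r$orientation <- x[9]
    } else r$gap_length <- as.numeric(x[6])
    r
  }))
}

#' @rdname write_agp
#' @export
assemble_from_agp <- function(agp, contigs) {
  out <- character(0)
  for (obj in unique(agp$object)) {
    rows <- agp[agp$object == obj, , drop = FALSE]
    rows <- rows[order(rows$part_number), , drop = FALSE]
    pieces <- vapply(seq_len(nrow(rows)), function(i) {
      r <- rows[i, ]
      if (r$component_type == "W") {
        s <- substr(contigs[[r$component_id]], r$component_beg,
                    r$component_end)
        if (identical(r$orientation, "-")) revcomp(s) else s
      } else strrep("N", r$gap_length)
    }, character(1))
    out[obj] <- paste(pieces, collapse = "")
  }
  out
}

# --- TSV -------------------------------------------------------------------

#' Read / write tab-separated tables with a header row
#'
#' @param x data.frame.
#' @param path file path.
#' @return `read_tsv` returns a data.frame.
#' @export
write_tsv <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
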
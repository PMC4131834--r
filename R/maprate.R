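# Unique-mapping-rate reports: uniquely mapped reads / total reads x 100
# for a read set against a reference. A read is unique when it has exactly
# one reported alignment with MAPQ at or above the floor and no
# secondary/supplementary flags; every read in the manifest is counted
# exactly once (pairs count as two reads).

#' Unique mapping rate of a read set against one reference
#'
#' @param sam SAM-subset data.frame of the read set aligned to one
#'   reference (pos 0-based; may include unmapped flag-4 records).
#' @param manifest character vector of all read names in the set (reads
#'   absent from the SAM count as unmapped; SAM reads missing from the
#'   manifest are counted with a warning).
#' @param read_set_id,reference_id labels for the report row.
#' @param min_mapq MAPQ floor for a unique alignment (default 20).
#' @return one-row data.frame: read_set_id, reference_id, total_reads,
#'   uniquely_mapped, multi_mapped, unmapped, unique_rate_pct.
#' @export
unique_mapping_rate <- function(sam, manifest, read_set_id = "reads",
                                reference_id = "ref", min_mapq = 20) {
  extra <- setdiff(unique(sam$qname), manifest)
  if (length(extra)) {
    warning(sprintf("%d read(s) in SAM missing from manifest; counted",
                    length(extra)))
    manifest <- c(manifest, extra)
  }
  primary <- bitwAnd(sam$flag, 256L) == 0 & bitwAnd(sam$flag, 2048L) == 0
  mapped <- primary & bitwAnd(sam$flag, 4L) == 0
  n_aln <- table(sam$qname[mapped])
  status <- setNames(rep("unmapped", length(manifest)), manifest)
  seen <- names(n_aln)
  uq <- sam$qname %in% seen[n_aln == 1] & mapped & sam$mapq >= min_mapq
  status[unique(sam$qname[mapped])] <- "multi"
  status[unique(sam$qname[uq])] <- "unique"
  total <- length(manifest)
  u <- sum(status == "unique"); m <- sum(status == "multi")
  un <- sum(status == "unmapped")
  stopifnot(u + m + un == total)
  data.frame(read_set_id = read_set_id, reference_id = reference_id,
             total_reads = total, uniquely_mapped = u, multi_mapped = m,
             unmapped = un,
             unique_rate_pct = if (total > 0) round(100 * u / total, 1) else 0)
}

#' Mapping-rate report across read sets and references
#'
#' @param sams nested list: `sams[[read_set]][[reference]]` is a SAM table.
#' @param manifests named list of read-name vectors per read set.
#' @param min_mapq MAPQ floor.
#' @return data.frame with one row per (read set, reference).
#' @export
mapping_report <- function(sams, manifests, min_mapq = 20) {
  rows <- list()
  for (rs in names(sams)) for (ref in names(sams[[rs]]))
    rows[[length(rows) + 1]] <-
      unique_mapping_rate(sams[[rs]][[ref]], manifests[[rs]], rs, ref,
                          min_mapq)
  do.call(rbind, rows)
}
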
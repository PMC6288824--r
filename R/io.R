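# Readers and writers for the formats the pipeline touches.
#
# Internal coordinates are 1-based inclusive (GFF3 convention); BED's
# 0-based half-open convention is converted only at the I/O boundary.

.cyto_cols <- c("chrom", "pos", "strand", "context", "meth_reads", "coverage")

#' Read a per-cytosine methylation count table
#'
#' Reads a methratio-style tab-separated table (columns chrom, pos, strand,
#' context, meth_reads, coverage; '#'-prefixed header; optionally gzipped),
#' validates counts, drops sites below the coverage filter, and returns the
#' records sorted by (chrom, pos, strand).
#'
#' @param path File path (plain or `.gz`).
#' @param min_coverage Minimum read coverage; sites below it are dropped
#'   (default 4).
#' @return Data.frame with the six canonical columns plus `level`
#'   (`meth_reads / coverage`).
#' @export
read_cytosine_table <- function(path, min_coverage = 4L) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (grepl("\\.gz$", path)) {
    # decompress once; fread has no native gz support in this configuration
    tmp <- tempfile(fileext = ".tsv")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(readLines(gzfile(path)), tmp)
    path <- tmp
  }
  first <- tryCatch(readLines(path, n = 1L), error = function(e) character(0))
  empty_out <- function() {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      strand = character(0), context = character(0),
                      meth_reads = integer(0), coverage = integer(0))
    out$level <- numeric(0)
    out
  }
  if (length(first) == 0L) return(empty_out())
  skip <- if (startsWith(first, "#")) 1L else 0L
  dt <- tryCatch(
    suppressWarnings(
      data.table::fread(path, header = FALSE, sep = "\t", skip = skip,
                        data.table = FALSE,
                        colClasses = list(character = c(1, 3, 4)))),
    error = function(e) {
      if (length(readLines(path)) <= skip) NULL else stop(e)
    })
  if (is.null(dt) || nrow(dt) == 0L) return(empty_out())
  if (ncol(dt) < length(.cyto_cols)) {
    stop("cytosine table needs columns: ", paste(.cyto_cols, collapse = ", "))
  }
  dt <- dt[, seq_along(.cyto_cols), drop = FALSE]
  names(dt) <- .cyto_cols
  dt$pos <- as.integer(dt$pos)
  dt$meth_reads <- as.integer(dt$meth_reads)
  dt$coverage <- as.integer(dt$coverage)
  bad <- which(is.na(dt$pos) | is.na(dt$meth_reads) | is.na(dt$coverage) |
                 !dt$strand %in% c("+", "-") |
                 !dt$context %in% c("CG", "CHG", "CHH"))
  if (length(bad)) {
    stop("malformed cytosine record at data line(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  over <- which(dt$meth_reads > dt$coverage)
  if (length(over)) {
    stop("meth_reads exceeds coverage at data line(s): ",
         paste(utils::head(over, 5L), collapse = ", "))
  }
  dt <- dt[dt$coverage >= min_coverage, , drop = FALSE]
  dt <- dt[order(dt$chrom, dt$pos, dt$strand), , drop = FALSE]
  rownames(dt) <- NULL
  dt$level <- ifelse(dt$coverage > 0L, dt$meth_reads / dt$coverage, NA_real_)
  dt
}

#' Write a per-cytosine methylation count table
#'
#' @param records Data.frame with the six canonical cytosine columns.
#' @param path Output path; `.gz` suffix writes gzip.
#' @export
write_cytosine_table <- function(records, path) {
  stopifnot(all(.cyto_cols %in% names(records)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(.cyto_cols, collapse = "\t")), con)
  if (nrow(records)) {
    writeLines(paste(records$chrom, records$pos, records$strand,
                     records$context, records$meth_reads, records$coverage,
                     sep = "\t"), con)
  }
  invisible(path)
}

#' Read gene and TE annotation
#'
#' Genes are read from GFF3 (via \pkg{rtracklayer}); TSS/TES are taken as
#' the annotated mRNA boundaries, parts are resolved to CDS/UTR/intron, and
#' introns are inferred as gaps between exons when not annotated. TEs are
#' read from GFF3 or BED (BED's 0-based half-open coordinates are converted
#' to 1-based inclusive).
#'
#' @param gff3_path Gene annotation GFF3.
#' @param te_path TE annotation, GFF3 or BED (by file extension).
#' @return A `dmrlink_annotation`-shaped list with `genes`, `parts`, `tes`
#'   (no sequences).
#' @export
read_annotation <- function(gff3_path, te_path = NULL) {
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p) if (length(p)) as.character(p[1]) else NA_character_,
                   character(1))

  mrna_idx <- which(type == "mRNA")
  genes <- list(); parts <- list()
  for (i in mrna_idx) {
    mid <- ids[i]
    gene_id <- if (!is.na(parent[i])) parent[i] else mid
    s <- GenomicRanges::start(gr)[i]; e <- GenomicRanges::end(gr)[i]
    str <- as.character(GenomicRanges::strand(gr)[i])
    if (!str %in% c("+", "-")) str <- "+"
    kids <- which(!is.na(parent) & parent == mid)
    ktype <- type[kids]
    ks <- GenomicRanges::start(gr)[kids]; ke <- GenomicRanges::end(gr)[kids]
    if (any(ks < s | ke > e)) {
      stop("child feature outside mRNA span for ", mid)
    }
    pr <- data.frame(gene_id = gene_id, type = ktype, start = ks, end = ke,
                     stringsAsFactors = FALSE)
    pr$type[pr$type %in% c("five_prime_UTR", "three_prime_UTR", "UTR")] <- "UTR"
    # infer introns from exon gaps
    ex <- pr[pr$type == "exon", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex) >= 2L) {
      istart <- ex$end[-nrow(ex)] + 1L
      iend <- ex$start[-1L] - 1L
      keep <- istart <= iend
      if (any(keep)) {
        pr <- rbind(pr, data.frame(gene_id = gene_id, type = "intron",
                                   start = istart[keep], end = iend[keep],
                                   stringsAsFactors = FALSE))
      }
    }
    pr <- pr[pr$type %in% c("CDS", "UTR", "intron"), , drop = FALSE]
    pr <- pr[order(pr$start), , drop = FALSE]
    genes[[mid]] <- data.frame(
      gene_id = gene_id, chrom = as.character(GenomicRanges::seqnames(gr)[i]),
      start = s, end = e, strand = str,
      tss = if (str == "+") s else e,
      tes = if (str == "+") e else s, stringsAsFactors = FALSE)
    parts[[mid]] <- pr
  }
  genes <- if (length(genes)) do.call(rbind, c(genes, list(make.row.names = FALSE))) else
    data.frame(gene_id = character(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0), tss = integer(0),
               tes = integer(0))
  parts <- if (length(parts)) do.call(rbind, c(parts, list(make.row.names = FALSE))) else
    data.frame(gene_id = character(0), type = character(0),
               start = integer(0), end = integer(0))

  tes <- data.frame(te_id = character(0), chrom = character(0),
                    start = integer(0), end = integer(0), family = character(0))
  if (!is.null(te_path)) {
    if (grepl("\\.bed(\\.gz)?$", te_path, ignore.case = TRUE)) {
      tg <- rtracklayer::import(te_path, format = "bed")
      fam <- rep("unknown", length(tg))
      nm <- S4Vectors::mcols(tg)$name
      if (!is.null(nm)) fam <- as.character(nm)
      tes <- data.frame(
        te_id = if (!is.null(nm)) as.character(nm) else
          paste0("te", seq_along(tg)),
        chrom = as.character(GenomicRanges::seqnames(tg)),
        start = GenomicRanges::start(tg), end = GenomicRanges::end(tg),
        family = fam, stringsAsFactors = FALSE)
    } else {
      tg <- rtracklayer::import(te_path, format = "gff3")
      tmd <- S4Vectors::mcols(tg)
      fam <- if (!is.null(tmd$family)) as.character(tmd$family) else
        rep("unknown", length(tg))
      tid <- if (!is.null(tmd$ID)) as.character(tmd$ID) else
        paste0("te", seq_along(tg))
      tes <- data.frame(
        te_id = tid, chrom = as.character(GenomicRanges::seqnames(tg)),
        start = GenomicRanges::start(tg), end = GenomicRanges::end(tg),
        family = fam, stringsAsFactors = FALSE)
    }
  }
  structure(list(sequences = NULL, genes = genes, parts = parts, tes = tes),
            class = "dmrlink_annotation")
}

#' Write DMRs as BED6
#'
#' BED uses 0-based half-open coordinates, so a 1-based inclusive DMR
#' `[start, end]` becomes `start-1, end`. Name is `context:direction`, score
#' is `round(1000 * |delta|)`, strand is `.` for CG/CHG (Watson-screened)
#' and the scan strand for CHH.
#'
#' @param dmrs Data.frame as returned by [call_dmrs()].
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# chrom start end name score strand (BED6; score = 1000*|delta|)",
             con)
  if (is.null(dmrs) || nrow(dmrs) == 0L) return(invisible(path))
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start, dmrs$end, dmrs$context), ,
               drop = FALSE]
  strand <- ifelse(dmrs$context == "CHH" & dmrs$strand_scope %in% c("watson", "crick"),
                   ifelse(dmrs$strand_scope == "watson", "+", "-"), ".")
  lines <- paste(dmrs$chrom, dmrs$start - 1L, dmrs$end,
                 paste0(dmrs$context, ":", dmrs$direction),
                 round(1000 * abs(dmrs$delta)), strand, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Load the packaged published-result fixtures
#'
#' Two small tables transcribed from the source study of photoperiod-induced
#' methylation change in cucumber shoot apices: `"table1"` holds the ten
#' differentially expressed TEs with their per-condition FPKM (LS =
#' low-temperature short-day, LL = low-temperature long-day) and every DMR
#' interval associated with each TE; `"table2"` holds the ten putative
#' epiregulated genes with their expression change and DMR descriptor
#' (placement, context, distance to TSS/TES, methylation delta).
#'
#' @param name `"table1"` or `"table2"`.
#' @return Data.frame (one row per TE-DMR or gene-DMR pairing).
#' @export
load_table_fixtures <- function(name = c("table1", "table2")) {
  name <- match.arg(name)
  f <- system.file("extdata",
                   switch(name,
                          table1 = "table1_det_dmr.tsv",
                          table2 = "table2_epiregulation.tsv"),
                   package = "dmrlink", mustWork = TRUE)
  utils::read.delim(f, stringsAsFactors = FALSE)
}

# --- writers used by the simulator / pipeline ------------------------------

write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(sequences), path)
  invisible(path)
}

write_annotation_gff3 <- function(annotation, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  g <- annotation$genes
  p <- annotation$parts
  for (i in seq_len(nrow(g))) {
    gid <- g$gene_id[i]
    writeLines(c(
      paste(g$chrom[i], "dmrlink", "gene", g$start[i], g$end[i], ".",
            g$strand[i], ".", paste0("ID=", gid), sep = "\t"),
      paste(g$chrom[i], "dmrlink", "mRNA", g$start[i], g$end[i], ".",
            g$strand[i], ".", paste0("ID=", gid, ".1;Parent=", gid), sep = "\t")
    ), con)
    pr <- p[p$gene_id == gid, , drop = FALSE]
    # exons = everything that is not intron, merged; needed for readers that
    # infer introns from exon gaps
    ex <- pr[pr$type != "intron", , drop = FALSE]
    ex <- ex[order(ex$start), , drop = FALSE]
    if (nrow(ex)) {
      merged <- list(c(ex$start[1], ex$end[1]))
      for (j in seq_len(nrow(ex))[-1]) {
        last <- merged[[length(merged)]]
        if (ex$start[j] <= last[2] + 1L) {
          merged[[length(merged)]][2] <- max(last[2], ex$end[j])
        } else merged[[length(merged) + 1L]] <- c(ex$start[j], ex$end[j])
      }
      for (m in merged) {
        writeLines(paste(g$chrom[i], "dmrlink", "exon", m[1], m[2], ".",
                         g$strand[i], ".", paste0("Parent=", gid, ".1"),
                         sep = "\t"), con)
      }
    }
    type_out <- c(CDS = "CDS", UTR = "UTR", intron = "intron")
    for (j in seq_len(nrow(pr))) {
      writeLines(paste(g$chrom[i], "dmrlink", type_out[[pr$type[j]]],
                       pr$start[j], pr$end[j], ".", g$strand[i],
                       if (pr$type[j] == "CDS") "0" else ".",
                       paste0("Parent=", gid, ".1"), sep = "\t"), con)
    }
  }
  invisible(path)
}

write_te_gff3 <- function(tes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(tes)) {
    writeLines(paste(tes$chrom, "dmrlink", "transposable_element",
                     tes$start, tes$end, ".", ".", ".",
                     paste0("ID=", tes$te_id, ";family=", tes$family),
                     sep = "\t"), con)
  }
  invisible(path)
}

write_te_bed <- function(tes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(tes)) {
    writeLines(paste(tes$chrom, tes$start - 1L, tes$end, tes$te_id, 0, ".",
                     sep = "\t"), con)
  }
  invisible(path)
}

write_tsv_with_header <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  invisible(path)
}
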
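# Direct-target triage from ChIP peaks: build each gene's intronic/intergenic
# search territory and call the gene a likely direct target when a peak for
# the factor of interest (Jumu) is clustered with a peak for at least one
# partner cardiogenic TF inside that territory.

CARDIOGENIC_TFS <- c("Jumu", "Myb", "Tin", "Tup", "Twi", "Su(H)", "Pnt",
                     "Mad", "Hand")

#' Intronic/intergenic search territory of a gene
#'
#' The territory where cardiac cis-regulatory modules are sought: the gene's
#' introns (gene span minus exons) plus the two intergenic intervals bounded
#' by the immediately adjacent 5' and 3' neighbor genes. A neighbor abutting
#' the gene contributes no interval on that side. Strand is ignored.
#'
#' @param gene `GRanges` of length 1: the gene span.
#' @param exons `GRanges` of the gene's exons (within the span), or `NULL` /
#'   empty when exon structure is unavailable, in which case the whole gene
#'   body is used as the intronic proxy with a warning (a conservative
#'   superset).
#' @param upstream_neighbor,downstream_neighbor `GRanges` of length 1: the
#'   adjacent gene on the lower- and higher-coordinate side, on the same
#'   chromosome and not overlapping the gene.
#' @return A sorted, disjoint `GRanges` of territory intervals.
#' @examples
#' library(GenomicRanges)
#' gene <- GRanges("chr2L", IRanges(1001, 1300))
#' exons <- GRanges("chr2L", IRanges(c(1001, 1201), c(1100, 1300)))
#' up <- GRanges("chr2L", IRanges(1, 500))
#' dn <- GRanges("chr2L", IRanges(2001, 2500))
#' gene_territory(gene, up, dn, exons = exons)
#' @export
gene_territory <- function(gene, upstream_neighbor, downstream_neighbor,
                           exons = NULL) {
  stopifnot(length(gene) == 1, length(upstream_neighbor) == 1,
            length(downstream_neighbor) == 1)
  chrom <- as.character(GenomicRanges::seqnames(gene))
  for (nb in list(upstream_neighbor, downstream_neighbor)) {
    if (as.character(GenomicRanges::seqnames(nb)) != chrom) {
      stop("neighbor genes must lie on the gene's chromosome")
    }
    if (IRanges::overlapsAny(nb, gene, ignore.strand = TRUE)) {
      stop("neighbor gene overlaps the gene span")
    }
  }
  if (GenomicRanges::end(upstream_neighbor) >= GenomicRanges::start(gene)) {
    stop("`upstream_neighbor` must end before the gene starts")
  }
  if (GenomicRanges::start(downstream_neighbor) <= GenomicRanges::end(gene)) {
    stop("`downstream_neighbor` must start after the gene ends")
  }

  if (is.null(exons) || length(exons) == 0) {
    warning("no exon structure supplied: using the whole gene body as the ",
            "intronic search region")
    intronic <- GenomicRanges::granges(gene)
  } else {
    if (!all(IRanges::overlapsAny(exons, gene, type = "within",
                                  ignore.strand = TRUE))) {
      stop("exons must lie within the gene span")
    }
    intronic <- GenomicRanges::setdiff(GenomicRanges::granges(gene),
                                       GenomicRanges::granges(exons),
                                       ignore.strand = TRUE)
  }

  pieces <- list(intronic)
  up_end <- GenomicRanges::end(upstream_neighbor)
  if (up_end + 1 <= GenomicRanges::start(gene) - 1) {
    pieces <- c(pieces, GenomicRanges::GRanges(
      chrom, IRanges::IRanges(up_end + 1, GenomicRanges::start(gene) - 1)))
  }
  dn_start <- GenomicRanges::start(downstream_neighbor)
  if (GenomicRanges::end(gene) + 1 <= dn_start - 1) {
    pieces <- c(pieces, GenomicRanges::GRanges(
      chrom, IRanges::IRanges(GenomicRanges::end(gene) + 1, dn_start - 1)))
  }
  territory <- do.call(c, pieces)
  GenomicRanges::strand(territory) <- "*"
  GenomicRanges::sort(GenomicRanges::reduce(territory))
}

#' Are two peaks clustered?
#'
#' Two peaks on the same chromosome are clustered when the gap between them is
#' at most `max_gap` base pairs; overlapping or abutting peaks have gap 0.
#' Symmetric in its arguments.
#'
#' @param peak_a,peak_b `GRanges` of length 1 on the same chromosome.
#' @param max_gap Maximum separating gap in bp (default 0: overlap/abutment).
#' @return Logical flag.
#' @examples
#' library(GenomicRanges)
#' clustered(GRanges("chr3R", IRanges(100, 200)),
#'           GRanges("chr3R", IRanges(150, 250)))         # TRUE
#' clustered(GRanges("chr3R", IRanges(100, 200)),
#'           GRanges("chr3R", IRanges(801, 900)), max_gap = 500)  # FALSE
#' @export
clustered <- function(peak_a, peak_b, max_gap = 0) {
  stopifnot(length(peak_a) == 1, length(peak_b) == 1, max_gap >= 0)
  if (as.character(GenomicRanges::seqnames(peak_a)) !=
      as.character(GenomicRanges::seqnames(peak_b))) {
    stop("peaks must lie on the same chromosome")
  }
  gap <- GenomicRanges::distance(peak_a, peak_b, ignore.strand = TRUE)
  !is.na(gap) && gap <= max_gap
}

#' Classify a gene as a likely direct target from ChIP peaks
#'
#' Restricts the peak set to peaks intersecting the gene's territory (peaks
#' partially overlapping the boundary count as inside), then applies the
#' direct-target criterion: no peak for the factor of interest in the
#' territory gives `no_jumu_peak` (regulation presumed indirect); a
#' factor-of-interest peak clustered (gap <= `max_gap`) with at least one
#' partner-TF peak gives `direct`, with the supporting TFs listed; a
#' factor-of-interest peak with no clustered partner gives `jumu_only`.
#'
#' @param territory `GRanges` from [gene_territory()].
#' @param peaks `GRanges` of ChIP peaks with a `tf` metadata column.
#' @param max_gap Clustering distance in bp (default 0 = overlap).
#' @param focus_tf The factor of interest (default `"Jumu"`).
#' @param tf_list Allowed TF names (default the nine cardiogenic TFs).
#' @param gene Optional gene name recorded in the call.
#' @return A one-row tibble: `gene`, `status`, `supporting_tfs`
#'   (comma-separated), `best_gap` (smallest focus-partner gap in bp, `NA`
#'   when undefined), `max_gap`.
#' @export
classify_direct_target <- function(territory, peaks, max_gap = 0,
                                   focus_tf = "Jumu",
                                   tf_list = CARDIOGENIC_TFS,
                                   gene = NA_character_) {
  if (length(territory) == 0) stop("empty gene territory")
  if (!("tf" %in% names(S4Vectors::mcols(peaks)))) {
    stop("`peaks` must carry a `tf` metadata column")
  }
  tf <- as.character(S4Vectors::mcols(peaks)$tf)
  bad <- setdiff(unique(tf), tf_list)
  if (length(bad) > 0) {
    stop("unknown TF name(s) in peaks: ", paste(bad, collapse = ", "))
  }
  inside <- IRanges::overlapsAny(peaks, territory, ignore.strand = TRUE)
  peaks <- peaks[inside]
  tf <- tf[inside]

  focus <- peaks[tf == focus_tf]
  if (length(focus) == 0) {
    return(tibble::tibble(gene = gene, status = "no_jumu_peak",
                          supporting_tfs = "", best_gap = NA_real_,
                          max_gap = max_gap))
  }
  partners <- peaks[tf != focus_tf]
  partner_tf <- tf[tf != focus_tf]
  if (length(partners) == 0) {
    return(tibble::tibble(gene = gene, status = "jumu_only",
                          supporting_tfs = "", best_gap = NA_real_,
                          max_gap = max_gap))
  }
  # pairwise focus x partner gaps
  gaps <- sapply(seq_along(partners), function(j) {
    min(GenomicRanges::distance(focus,
                                rep(partners[j], length(focus)),
                                ignore.strand = TRUE), na.rm = TRUE)
  })
  supp <- sort(unique(partner_tf[gaps <= max_gap]))
  best <- suppressWarnings(min(gaps))
  if (length(supp) > 0) {
    tibble::tibble(gene = gene, status = "direct",
                   supporting_tfs = paste(supp, collapse = ","),
                   best_gap = best, max_gap = max_gap)
  } else {
    tibble::tibble(gene = gene, status = "jumu_only", supporting_tfs = "",
                   best_gap = best, max_gap = max_gap)
  }
}

#' Read ChIP peaks from BED files
#'
#' Reads one or more BED files into a pooled `GRanges` with a `tf` metadata
#' column. With several files, each file's TF is taken from the names of
#' `paths` (or the file name stem); with a single pooled file, the BED name
#' column is used.
#'
#' @param paths Character vector of BED file paths, optionally named by TF.
#' @return `GRanges` with a `tf` column.
#' @export
read_peaks_bed <- function(paths) {
  labels <- names(paths)
  if (is.null(labels)) {
    labels <- sub("\\.bed$", "", basename(paths), ignore.case = TRUE)
  }
  pieces <- lapply(seq_along(paths), function(i) {
    gr <- rtracklayer::import(paths[i], format = "BED")
    tf_col <- S4Vectors::mcols(gr)$name
    S4Vectors::mcols(gr) <- NULL
    if (length(paths) == 1 && !is.null(tf_col)) {
      S4Vectors::mcols(gr)$tf <- as.character(tf_col)
    } else {
      S4Vectors::mcols(gr)$tf <- labels[i]
    }
    gr
  })
  do.call(c, pieces)
}

#' Write ChIP peaks to a BED file
#'
#' Writes a `GRanges` with a `tf` metadata column as BED, placing the TF in
#' the name column, so [read_peaks_bed()] round-trips it.
#'
#' @param peaks `GRanges` with a `tf` column.
#' @param path Output BED path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  gr <- GenomicRanges::granges(peaks)
  S4Vectors::mcols(gr)$name <- as.character(S4Vectors::mcols(peaks)$tf)
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Triage several genes at once
#'
#' @param genes Named list; each element a list with `gene`, `upstream`,
#'   `downstream` (`GRanges`, length 1) and optionally `exons`.
#' @param peaks `GRanges` with a `tf` column.
#' @inheritParams classify_direct_target
#' @return A tibble with one [classify_direct_target()] row per gene.
#' @export
triage_genes <- function(genes, peaks, max_gap = 0, focus_tf = "Jumu",
                         tf_list = CARDIOGENIC_TFS) {
  out <- lapply(names(genes), function(nm) {
    g <- genes[[nm]]
    terr <- gene_territory(g$gene, g$upstream, g$downstream,
                           exons = g$exons)
    chrom <- as.character(GenomicRanges::seqnames(g$gene))
    on_chrom <- as.character(GenomicRanges::seqnames(peaks)) == chrom
    classify_direct_target(terr, peaks[on_chrom], max_gap = max_gap,
                           focus_tf = focus_tf, tf_list = tf_list, gene = nm)
  })
  do.call(rbind, out)
}
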
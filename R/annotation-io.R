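#' Read gene models and site-class annotations
#'
#' Gene models come as BED3+ (0-based half-open intervals) with the gene id
#' in column 4 and GC content (fraction of the gene, in `[0,1]`) in column 5.
#' Site classes come as a TSV with columns `contig`, `pos` (1-based, matching
#' sync coordinates), `gene_id`, `class` (`NS`, `SYN` or `OTHER`).
#'
#' Every classified site must fall inside its gene's interval; sites outside
#' are dropped with a warning. Duplicate gene ids are an error.
#'
#' @param bed_path path to the BED file of gene intervals.
#' @param siteclass_path path to the site-class TSV.
#' @return list with `genes` (data.frame `gene_id`, `contig`, `start`, `end`,
#'   `length`, `gc_content`) and `site_classes` (data.frame `contig`, `pos`,
#'   `gene_id`, `class`).
#' @export
read_gene_annotation <- function(bed_path, siteclass_path) {
  bed <- data.table::fread(bed_path, header = FALSE, sep = "\t",
                           showProgress = FALSE)
  if (ncol(bed) < 5L) stop("gene BED needs >= 5 columns (chrom, start, end, name, gc)")
  genes <- data.frame(gene_id = as.character(bed[[4L]]),
                      contig = as.character(bed[[1L]]),
                      start = as.integer(bed[[2L]]),
                      end = as.integer(bed[[3L]]),
                      gc_content = as.numeric(bed[[5L]]),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in BED: ",
         genes$gene_id[duplicated(genes$gene_id)][1L])
  }
  if (any(genes$start >= genes$end)) stop("BED interval with start >= end")
  if (any(genes$gc_content < 0 | genes$gc_content > 1, na.rm = TRUE)) {
    stop("gc_content outside [0, 1]")
  }
  genes$length <- genes$end - genes$start

  sc <- data.table::fread(siteclass_path, header = TRUE, sep = "\t",
                          showProgress = FALSE)
  need <- c("contig", "pos", "gene_id", "class")
  if (!all(need %in% names(sc))) {
    stop("site-class table must have columns: ", paste(need, collapse = ", "))
  }
  sc <- data.frame(contig = as.character(sc$contig), pos = as.integer(sc$pos),
                   gene_id = as.character(sc$gene_id),
                   class = as.character(sc$class), stringsAsFactors = FALSE)
  if (!all(sc$class %in% c("NS", "SYN", "OTHER"))) {
    stop("site class must be NS, SYN or OTHER")
  }
  gi <- match(sc$gene_id, genes$gene_id)
  if (anyNA(gi)) {
    stop("site-class entry for unknown gene_id: ",
         sc$gene_id[which(is.na(gi))[1L]])
  }
  # 1-based site pos inside 0-based half-open [start, end) means
  # start < pos <= end
  inside <- sc$contig == genes$contig[gi] &
    sc$pos > genes$start[gi] & sc$pos <= genes$end[gi]
  if (any(!inside)) {
    warning(sum(!inside), " classified site(s) fall outside their gene interval; dropped")
    sc <- sc[inside, , drop = FALSE]
  }
  list(genes = genes[, c("gene_id", "contig", "start", "end", "length",
                         "gc_content")],
       site_classes = sc)
}

#' Read a gene-class membership table
#'
#' TSV with columns `gene_id`, `label`; one row per (gene, label) pair.
#' @param path path to the TSV.
#' @param genes optional gene table from [read_gene_annotation()]; if given,
#'   labels for unknown genes are an error.
#' @return data.frame with `gene_id`, `label`.
#' @export
read_gene_classes <- function(path, genes = NULL) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  if (!all(c("gene_id", "label") %in% names(x))) {
    stop("gene-class table must have columns gene_id, label")
  }
  out <- data.frame(gene_id = as.character(x$gene_id),
                    label = as.character(x$label), stringsAsFactors = FALSE)
  if (!is.null(genes) && !all(out$gene_id %in% genes$gene_id)) {
    stop("gene-class table labels a gene absent from the gene models")
  }
  out
}

#' Read a term-to-gene map
#'
#' TSV with columns `term_id`, `gene_id`; one row per (term, gene) pair.
#' @param path path to the TSV.
#' @return named list mapping term_id to a character vector of gene ids.
#' @export
read_term_map <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  if (!all(c("term_id", "gene_id") %in% names(x))) {
    stop("term map must have columns term_id, gene_id")
  }
  split(as.character(x$gene_id), as.character(x$term_id))
}

#' Read a gene-expression table
#'
#' TSV with columns `gene_id`, `fpkm`, `log2fc_sex`, `bias_class`.
#' `log2fc_sex` follows the female-minus-male convention (positive values are
#' female-biased); `bias_class` is `FBG`, `MBG` or `UNBIASED`.
#'
#' @param path path to the TSV.
#' @return data.frame with the four columns, validated.
#' @export
read_expression <- function(path) {
  x <- data.table::fread(path, header = TRUE, sep = "\t", showProgress = FALSE)
  need <- c("gene_id", "fpkm", "log2fc_sex", "bias_class")
  if (!all(need %in% names(x))) {
    stop("expression table must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(gene_id = as.character(x$gene_id),
                    fpkm = as.numeric(x$fpkm),
                    log2fc_sex = as.numeric(x$log2fc_sex),
                    bias_class = as.character(x$bias_class),
                    stringsAsFactors = FALSE)
  if (any(out$fpkm < 0, na.rm = TRUE)) stop("fpkm must be >= 0")
  if (!all(out$bias_class %in% c("FBG", "MBG", "UNBIASED"))) {
    stop("bias_class must be FBG, MBG or UNBIASED")
  }
  out
}

#' Write a per-gene statistics table as TSV
#'
#' Deterministic column order (as supplied), `NA` for missing values,
#' re-readable with [read_gene_stats()] to an equal table.
#'
#' @param table data.frame, one row per gene (or gene x pair).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gene_stats <- function(table, path) {
  stopifnot(is.data.frame(table))
  data.table::fwrite(table, path, sep = "\t", na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a per-gene statistics table written by [write_gene_stats()]
#' @param path path to the TSV.
#' @return data.frame.
#' @export
read_gene_stats <- function(path) {
  as.data.frame(data.table::fread(path, header = TRUE, sep = "\t",
                                  na.strings = "NA", showProgress = FALSE))
}
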
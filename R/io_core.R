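## Readers/writers for the tabular formats the pipeline touches, plus
## gene-level harmonisation and cohort assembly.
##
## Conventions (fixed across the package):
##   * expression / copy-number matrices: TSV, first column "gene_id",
##     remaining columns one per sample; numeric values written with 6
##     significant digits.
##   * segments: SEG-style TSV with header sample, chromosome, start, end,
##     log2ratio; coordinates 1-based inclusive on both ends.
##   * mutations: minimal MAF-like TSV (gene_id, sample_id, variant_class).
##   * clinical: TSV (sample_id, time_years, event, age, stage, subtype).
##   * annotation: BED-like TSV plus cytoband and is_metabolic columns.

#' Read an expression or copy-number matrix
#'
#' Reads a tab-separated matrix whose first column is `gene_id` and whose
#' remaining columns are samples. Optionally applies the `log2(x + 1)`
#' transform used for count-like abundance data; the pseudocount of 1 maps
#' zero-read genes to 0, which is what the zero-heavy gene filter
#' ([filter_zero_heavy_genes()]) expects.
#'
#' @param path Path to a TSV file.
#' @param log2_transform If `TRUE`, values become `log2(x + 1)`.
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames.
#' @export
read_expression <- function(path, log2_transform = FALSE) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("expected a gene_id column plus >=1 sample column")
  gene_id <- df[[1L]]
  dup <- gene_id[duplicated(gene_id)]
  if (length(dup) > 0L) {
    stop("duplicate gene_id in ", path, ": ", paste(unique(dup), collapse = ", "))
  }
  vals <- as.matrix(df[, -1L, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  bad <- which(is.na(num) & !(vals %in% c("NA", "")), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' at gene %s, sample %s",
                 vals[bad[1L, 1L], bad[1L, 2L]], gene_id[bad[1L, 1L]],
                 colnames(vals)[bad[1L, 2L]]))
  }
  rownames(num) <- gene_id
  colnames(num) <- colnames(df)[-1L]
  if (log2_transform) num <- log2(num + 1)
  num
}

#' Write an expression-shaped matrix
#'
#' Inverse of [read_expression()]. Values are formatted with 6 significant
#' digits, so writing, reading and writing again is byte-stable.
#'
#' @param mat Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @export
write_expression <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  fmt <- ifelse(is.na(mat), "NA", sprintf("%.6g", mat))
  dim(fmt) <- dim(mat)
  lines <- c(paste(c("gene_id", colnames(mat)), collapse = "\t"),
             paste(rownames(mat), apply(fmt, 1L, paste, collapse = "\t"),
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Remove genes with too many zero values
#'
#' Genes for which the fraction of zero-valued samples strictly exceeds
#' `max_zero_fraction` are dropped (on the raw or `log2(x + 1)` scale zero
#' reads map to value 0 either way). A gene with exactly the threshold
#' fraction of zeros is retained.
#'
#' @param expr Expression matrix (genes x samples).
#' @param max_zero_fraction Maximum tolerated fraction of zeros, default 0.75.
#' @return The matrix restricted to surviving genes, order preserved.
#' @export
filter_zero_heavy_genes <- function(expr, max_zero_fraction = 0.75) {
  zero_frac <- rowMeans(expr == 0)
  expr[zero_frac <= max_zero_fraction, , drop = FALSE]
}

#' Collapse probe-level rows to gene level
#'
#' For each gene keeps the probe with the largest sample standard deviation;
#' ties are broken deterministically by the lexicographically smallest probe
#' id. Genes with no probes are absent from the output.
#'
#' @param probe_expr Probe x sample matrix with probe ids as rownames.
#' @param probe_to_gene Named character vector mapping probe id -> gene id
#'   (each probe maps to at most one gene).
#' @return Gene x sample matrix.
#' @export
collapse_probes <- function(probe_expr, probe_to_gene) {
  probes <- intersect(rownames(probe_expr), names(probe_to_gene))
  if (length(probes) == 0L) {
    return(probe_expr[integer(0L), , drop = FALSE])
  }
  sds <- apply(probe_expr[probes, , drop = FALSE], 1L, sd)
  ## sort by gene, then descending sd, then probe id: first row per gene wins
  ord <- order(probe_to_gene[probes], -sds, probes)
  probes <- probes[ord]
  keep <- probes[!duplicated(probe_to_gene[probes])]
  out <- probe_expr[keep, , drop = FALSE]
  rownames(out) <- unname(probe_to_gene[keep])
  out
}

#' Read a SEG-style segment table
#'
#' Columns: sample, chromosome, start, end, log2ratio. Coordinates are taken
#' as 1-based and inclusive on both ends (the common SEG dialect).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with those five columns.
#' @export
read_segments <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  need <- c("sample", "chromosome", "start", "end", "log2ratio")
  if (!all(need %in% names(df))) {
    stop("segment file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  validate_segments(df)
  df
}

validate_segments <- function(segs) {
  if (any(segs$start > segs$end)) stop("segment with start > end")
  for (key in unique(paste(segs$sample, segs$chromosome))) {
    idx <- paste(segs$sample, segs$chromosome) == key
    s <- segs[idx, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1L && any(s$start[-1L] <= s$end[-nrow(s)])) {
      stop("overlapping segments for ", key)
    }
  }
  invisible(segs)
}

#' Map segmented copy number to gene level
#'
#' Each gene's value for a sample is the segment-length-weighted mean log2
#' ratio of the segments overlapping the gene body; genes untouched by any
#' segment get `NA`. Overlap lengths are computed on 1-based inclusive
#' coordinates, so a segment covering exactly one base has length 1.
#'
#' @param segs Segment data.frame as returned by [read_segments()].
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @return Gene x sample numeric matrix (genes in annotation order).
#' @export
segments_to_gene_matrix <- function(segs, ann) {
  validate_segments(segs)
  samples <- unique(segs$sample)
  out <- matrix(NA_real_, nrow = nrow(ann), ncol = length(samples),
                dimnames = list(ann$gene_id, samples))
  for (smp in samples) {
    s_all <- segs[segs$sample == smp, , drop = FALSE]
    for (chrom in unique(s_all$chromosome)) {
      s <- s_all[s_all$chromosome == chrom, , drop = FALSE]
      g <- which(ann$chromosome == chrom)
      for (i in g) {
        ov <- pmin(ann$end[i], s$end) - pmax(ann$start[i], s$start) + 1
        hit <- ov > 0
        if (any(hit)) {
          out[i, smp] <- sum(ov[hit] * s$log2ratio[hit]) / sum(ov[hit])
        }
      }
    }
  }
  out
}

#' Read a minimal somatic-mutation table
#'
#' @param path TSV with columns gene_id, sample_id, variant_class.
#' @return data.frame with those columns.
#' @export
read_mutations <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "sample_id", "variant_class")
  if (!all(need %in% names(df))) {
    stop("mutation file must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df[need])) stop("duplicate (gene, sample, class) mutation rows")
  df[need]
}

#' Read a clinical table
#'
#' @param path TSV with columns sample_id, time_years, event, age, stage,
#'   subtype. `stage` and `subtype` may be NA.
#' @return data.frame with columns sample_id, time (years), event (logical),
#'   age, stage (integer 1-4 or NA), subtype.
#' @export
read_clinical <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                   na.strings = c("NA", ""))
  need <- c("sample_id", "time_years", "event", "age", "stage", "subtype")
  if (!all(need %in% names(df))) {
    stop("clinical file must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    time = as.numeric(df$time_years),
                    event = as.logical(df$event),
                    age = as.numeric(df$age),
                    stage = as.integer(df$stage),
                    subtype = as.character(df$subtype),
                    stringsAsFactors = FALSE)
  if (any(out$time < 0, na.rm = TRUE)) stop("negative survival time")
  out
}

#' Read a gene annotation table
#'
#' @param path BED-like TSV with columns gene_id, chromosome, start, end,
#'   cytoband, is_metabolic.
#' @return data.frame with those columns (`is_metabolic` logical).
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "chromosome", "start", "end", "cytoband", "is_metabolic")
  if (!all(need %in% names(df))) {
    stop("annotation file must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[need]
  df$is_metabolic <- as.logical(df$is_metabolic)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene_id in annotation")
  if (any(df$start > df$end)) stop("annotation with start > end")
  if (any(!nzchar(df$chromosome))) stop("empty chromosome in annotation")
  df
}

#' Read a plain gene-list file (one gene id per line)
#' @param path Path to the file.
#' @return Character vector of gene ids.
#' @export
read_gene_list <- function(path) {
  x <- readLines(path)
  x[nzchar(trimws(x))]
}

#' Assemble a harmonised cohort bundle
#'
#' Intersects gene and sample sets across the data layers and reorders every
#' layer to match; intersection order follows the tumour expression matrix.
#' Clinical rows are restricted to tumour samples. Missing expression values
#' are disallowed; missing copy-number values are allowed (they propagate and
#' are excluded pairwise from correlations downstream).
#'
#' @param name Cohort name.
#' @param tumour_expr,normal_expr Gene x sample log2 expression matrices
#'   (`normal_expr` may be `NULL`).
#' @param cn_log2 Gene x sample copy-number log2-ratio matrix.
#' @param mutations Mutation data.frame (see [read_mutations()]).
#' @param clinical Clinical data.frame (see [read_clinical()]).
#' @param annotation Annotation data.frame (see [read_annotation()]).
#' @param hypoxia_signature Character vector of signature gene ids.
#' @return An object of class `cohort_bundle`: a list with the harmonised
#'   layers plus `scna_calls` (filled by [add_scna_calls()], initially NULL).
#' @export
cohort_bundle <- function(name, tumour_expr, cn_log2, mutations, clinical,
                          annotation, hypoxia_signature,
                          normal_expr = NULL) {
  if (anyNA(tumour_expr)) stop("missing values in tumour expression")
  if (!is.null(normal_expr) && anyNA(normal_expr)) {
    stop("missing values in normal expression")
  }
  genes <- intersect(rownames(tumour_expr), rownames(cn_log2))
  genes <- genes[genes %in% annotation$gene_id]
  genes <- rownames(tumour_expr)[rownames(tumour_expr) %in% genes]
  samples <- intersect(colnames(tumour_expr), colnames(cn_log2))
  samples <- colnames(tumour_expr)[colnames(tumour_expr) %in% samples]
  if (length(genes) == 0L || length(samples) == 0L) {
    stop("harmonisation left no genes or no samples")
  }
  if (!is.null(normal_expr)) {
    genes <- genes[genes %in% rownames(normal_expr)]
    normal_expr <- normal_expr[genes, , drop = FALSE]
  }
  obj <- list(
    name = name,
    tumour_expr = tumour_expr[genes, samples, drop = FALSE],
    normal_expr = normal_expr,
    cn_log2 = cn_log2[genes, samples, drop = FALSE],
    scna_calls = NULL,
    mutations = mutations[mutations$gene_id %in% genes &
                            mutations$sample_id %in% samples, , drop = FALSE],
    clinical = clinical[clinical$sample_id %in% samples, , drop = FALSE],
    annotation = annotation[match(genes, annotation$gene_id), , drop = FALSE],
    hypoxia_signature = hypoxia_signature
  )
  class(obj) <- "cohort_bundle"
  obj
}

#' Attach discrete SCNA calls to a bundle
#'
#' @param bundle A `cohort_bundle`.
#' @return The bundle with `scna_calls` set to [call_scna()] of its
#'   `cn_log2` layer.
#' @export
add_scna_calls <- function(bundle) {
  bundle$scna_calls <- call_scna(bundle$cn_log2)
  bundle
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("cohort_bundle '", x$name, "': ", nrow(x$tumour_expr), " genes, ",
      ncol(x$tumour_expr), " tumour samples",
      if (!is.null(x$normal_expr)) paste0(", ", ncol(x$normal_expr), " normals"),
      "\n", sep = "")
  invisible(x)
}

#' Write a cohort bundle to a directory in the package's file formats
#'
#' @param bundle A `cohort_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression(bundle$tumour_expr, file.path(dir, "tumour_expr.tsv"))
  if (!is.null(bundle$normal_expr)) {
    write_expression(bundle$normal_expr, file.path(dir, "normal_expr.tsv"))
  }
  write_expression(bundle$cn_log2, file.path(dir, "cn_log2.tsv"))
  write.table(data.frame(gene_id = bundle$mutations$gene_id,
                         sample_id = bundle$mutations$sample_id,
                         variant_class = bundle$mutations$variant_class),
              file.path(dir, "mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cl <- bundle$clinical
  write.table(data.frame(sample_id = cl$sample_id, time_years = cl$time,
                         event = cl$event, age = cl$age, stage = cl$stage,
                         subtype = cl$subtype),
              file.path(dir, "clinical.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(bundle$annotation, file.path(dir, "annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(bundle$hypoxia_signature, file.path(dir, "hypoxia_signature.txt"))
  invisible(dir)
}

#' Read a cohort bundle previously written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @param name Cohort name (defaults to the directory basename).
#' @return A harmonised `cohort_bundle` with SCNA calls attached.
#' @export
read_cohort <- function(dir, name = basename(dir)) {
  normal_path <- file.path(dir, "normal_expr.tsv")
  bundle <- cohort_bundle(
    name = name,
    tumour_expr = read_expression(file.path(dir, "tumour_expr.tsv")),
    normal_expr = if (file.exists(normal_path)) read_expression(normal_path),
    cn_log2 = read_expression(file.path(dir, "cn_log2.tsv")),
    mutations = read_mutations(file.path(dir, "mutations.tsv")),
    clinical = read_clinical(file.path(dir, "clinical.tsv")),
    annotation = read_annotation(file.path(dir, "annotation.tsv")),
    hypoxia_signature = read_gene_list(file.path(dir, "hypoxia_signature.txt"))
  )
  add_scna_calls(bundle)
}
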
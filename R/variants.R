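# Variant ingestion (VCF / annotated TSV) and the two screening steps:
# the alpha population-allele-frequency filter and the inheritance-mode
# filter.

.variant_cols <- c("chrom", "pos", "ref", "alt", "gene", "genotype",
                   "pop_af", "consequence", "insilico", "assertion",
                   "hotspot", "control_hom", "case_control", "known_change",
                   "repeat_region", "splice_impact", "acmg_codes")

#' Default semantic-field map for annotated variant input
#'
#' Maps each semantic field the rule engine understands to the VCF INFO key
#' (or TSV column name) that carries it. `gene` and `af` are required; all
#' other fields are optional and the corresponding rules stay silent when
#' they are absent.
#'
#' @return Named character vector.
#' @export
default_field_map <- function() {
  c(gene = "GENE", af = "AF", consequence = "CSQ", insilico = "INSILICO",
    assertion = "ASSERT", hotspot = "HOTSPOT", control_hom = "CTRLHOM",
    case_control = "CASECTRL", known_change = "KNOWN",
    repeat_region = "REPEATRGN", splice_impact = "SPLICE", acmg = "ACMG")
}

empty_variants <- function() {
  data.frame(chrom = character(0), pos = integer(0), ref = character(0),
             alt = character(0), gene = character(0), genotype = character(0),
             pop_af = numeric(0), consequence = character(0),
             insilico = numeric(0), assertion = character(0),
             hotspot = logical(0), control_hom = logical(0),
             case_control = logical(0), known_change = character(0),
             repeat_region = logical(0), splice_impact = logical(0),
             acmg_codes = character(0), stringsAsFactors = FALSE)
}

as_flag <- function(x) {
  if (length(x) != 1L || is.na(x)) return(NA)
  if (is.logical(x)) return(x)
  x %in% c("1", "TRUE", "true", "T", "yes")
}

as_num <- function(x) {
  if (length(x) != 1L || is.na(x) || identical(x, ".")) return(NA_real_)
  suppressWarnings(as.numeric(x))
}

as_chr <- function(x) {
  if (length(x) != 1L || is.na(x) || identical(x, ".")) return(NA_character_)
  as.character(x)
}

#' Read annotated variants from VCF or a tab-delimited table
#'
#' VCF 4.x records are read through vcfR; annotations come from INFO keys
#' named by `field_map` and the genotype from the first sample's GT.
#' Multiallelic records are split into one row per ALT allele, with
#' per-allele (`Number=A`) allele frequencies distributed by allele index;
#' alleles the first sample does not carry are dropped. For tab-delimited
#' input the file must carry `CHROM`, `POS`, `REF`, `ALT`, `GT` columns plus
#' the mapped annotation columns; `GT` holds `het`, `hom_alt`, `hemi` or a
#' VCF-style genotype string.
#'
#' Missing allele frequency (`.` or absent key) is recorded as `NA`, which
#' is distinct from 0: absence from population databases is treated as
#' evidence of rarity downstream. Unparsable rows are skipped with a
#' warning and counted in the `n_skipped` attribute.
#'
#' @param path Input file path.
#' @param format `"auto"` (by extension), `"vcf"` or `"tsv"`.
#' @param field_map Semantic-field map; must name `gene` and `af` sources.
#' @return Variant `data.frame` (one row per biallelic ALT) with attribute
#'   `n_skipped`.
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          field_map = default_field_map()) {
  format <- match.arg(format)
  miss <- setdiff(c("gene", "af"), names(field_map))
  if (length(miss)) {
    stop("field_map is missing required field(s): ", paste(miss, collapse = ", "))
  }
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "vcf") read_variants_vcf(path, field_map)
  else read_variants_tsv(path, field_map)
}

read_variants_vcf <- function(path, field_map) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  n <- nrow(v@fix)
  if (n == 0L) {
    out <- empty_variants()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  gt_raw <- tryCatch(vcfR::extract.gt(v)[, 1],
                     error = function(e) rep(NA_character_, n))
  info <- function(sem) {
    key <- field_map[[sem]]
    if (is.null(key) || is.na(key)) return(rep(NA_character_, n))
    out <- tryCatch(vcfR::extract.info(v, element = key),
                    error = function(e) rep(NA_character_, n))
    if (length(out) != n) rep(NA_character_, n) else out
  }
  gene_i <- info("gene"); af_i <- info("af"); csq_i <- info("consequence")
  ins_i <- info("insilico"); asr_i <- info("assertion")
  hot_i <- info("hotspot"); chom_i <- info("control_hom")
  cc_i <- info("case_control"); known_i <- info("known_change")
  rep_i <- info("repeat_region"); spl_i <- info("splice_impact")
  acmg_i <- info("acmg")

  rows <- list()
  skipped <- 0L
  for (i in seq_len(n)) {
    pos <- suppressWarnings(as.integer(fix[i, "POS"]))
    gt <- gt_raw[i]
    gene <- as_chr(gene_i[i])
    if (is.na(pos) || pos < 1L || is.na(gt) || is.na(gene)) {
      skipped <- skipped + 1L
      warning(sprintf("skipping unparsable VCF record %d (%s:%s)",
                      i, fix[i, "CHROM"], fix[i, "POS"]))
      next
    }
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    af_parts <- if (is.na(af_i[i])) character(0)
                else strsplit(af_i[i], ",", fixed = TRUE)[[1]]
    alleles <- strsplit(gt, "[/|]")[[1]]
    for (j in seq_along(alts)) {
      cnt <- sum(alleles == as.character(j))
      if (cnt == 0L) next
      geno <- if (length(alleles) == 1L) "hemi"
              else if (cnt >= 2L) "hom_alt" else "het"
      af_j <- if (length(af_parts) >= j) as_num(af_parts[j]) else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = fix[i, "CHROM"], pos = pos, ref = fix[i, "REF"],
        alt = alts[j], gene = gene, genotype = geno, pop_af = af_j,
        consequence = as_chr(csq_i[i]), insilico = as_num(ins_i[i]),
        assertion = as_chr(asr_i[i]), hotspot = as_flag(hot_i[i]),
        control_hom = as_flag(chom_i[i]), case_control = as_flag(cc_i[i]),
        known_change = as_chr(known_i[i]), repeat_region = as_flag(rep_i[i]),
        splice_impact = as_flag(spl_i[i]), acmg_codes = as_chr(acmg_i[i]),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else empty_variants()
  attr(out, "n_skipped") <- skipped
  out
}

read_variants_tsv <- function(path, field_map) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  base_cols <- c("CHROM", "POS", "REF", "ALT", "GT")
  miss_base <- setdiff(base_cols, names(df))
  if (length(miss_base)) {
    stop("variant table is missing column(s): ", paste(miss_base, collapse = ", "))
  }
  for (req in c("gene", "af")) {
    if (!(field_map[[req]] %in% names(df))) {
      stop("variant table is missing mapped column for '", req, "': ",
           field_map[[req]])
    }
  }
  col <- function(sem) {
    key <- field_map[[sem]]
    if (!is.null(key) && !is.na(key) && key %in% names(df)) df[[key]]
    else rep(NA, nrow(df))
  }
  geno_norm <- function(g) {
    if (is.na(g)) return(NA_character_)
    g <- as.character(g)
    if (g %in% c("het", "hom_alt", "hemi")) return(g)
    alleles <- strsplit(g, "[/|]")[[1]]
    cnt <- sum(alleles == "1")
    if (length(alleles) == 1L && cnt == 1L) return("hemi")
    if (cnt >= 2L) return("hom_alt")
    if (cnt == 1L) return("het")
    NA_character_
  }
  rows <- list()
  skipped <- 0L
  gene_v <- col("gene"); af_v <- col("af"); csq_v <- col("consequence")
  ins_v <- col("insilico"); asr_v <- col("assertion"); hot_v <- col("hotspot")
  chom_v <- col("control_hom"); cc_v <- col("case_control")
  known_v <- col("known_change"); rep_v <- col("repeat_region")
  spl_v <- col("splice_impact"); acmg_v <- col("acmg")
  for (i in seq_len(nrow(df))) {
    pos <- suppressWarnings(as.integer(df$POS[i]))
    geno <- geno_norm(df$GT[i])
    gene <- as_chr(gene_v[i])
    ref <- as.character(df$REF[i]); alt <- as.character(df$ALT[i])
    if (is.na(pos) || pos < 1L || is.na(geno) || is.na(gene) ||
        !nzchar(ref) || !nzchar(alt) || identical(ref, alt)) {
      skipped <- skipped + 1L
      warning(sprintf("skipping unparsable variant row %d", i))
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = as.character(df$CHROM[i]), pos = pos, ref = ref, alt = alt,
      gene = gene, genotype = geno, pop_af = as_num(af_v[i]),
      consequence = as_chr(csq_v[i]), insilico = as_num(ins_v[i]),
      assertion = as_chr(asr_v[i]), hotspot = as_flag(hot_v[i]),
      control_hom = as_flag(chom_v[i]), case_control = as_flag(cc_v[i]),
      known_change = as_chr(known_v[i]), repeat_region = as_flag(rep_v[i]),
      splice_impact = as_flag(spl_v[i]), acmg_codes = as_chr(acmg_v[i]),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
         else empty_variants()
  attr(out, "n_skipped") <- skipped
  out
}

#' Population allele-frequency screen
#'
#' Keeps variants whose population allele frequency is missing or at most
#' `alpha` (inclusive boundary: borderline variants are left for the
#' downstream evidence engine to adjudicate; absence from population
#' databases cannot exclude a variant). Input order is preserved and the
#' number of removed variants is recorded in the `n_removed` attribute.
#'
#' @param variants Variant `data.frame`.
#' @param alpha Frequency threshold in `[0, 1]` (default 0.1).
#' @return Filtered variant `data.frame`.
#' @export
filter_af <- function(variants, alpha = 0.1) {
  stopifnot(is.numeric(alpha), alpha >= 0, alpha <= 1)
  keep <- is.na(variants$pop_af) | variants$pop_af <= alpha
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(!keep)
  out
}

#' Gene-to-inheritance-mode map from a gene-disease table
#'
#' @param gene_disease `data.frame` with columns `gene`, `disease_id`,
#'   `inheritance`.
#' @return Named list: gene -> character vector of modes.
#' @export
gene_modes <- function(gene_disease) {
  lapply(split(as.character(gene_disease$inheritance), gene_disease$gene),
         unique)
}

#' Inheritance-mode screen
#'
#' Per gene, keeps the variants whose single-sample genotype is compatible
#' with at least one disease-linked inheritance mode:
#' \itemize{
#'   \item AD / XLD: any genotype qualifies.
#'   \item AR: qualifies only when the gene carries a homozygous-alternate
#'     variant or at least two distinct heterozygous variants (putative
#'     compound heterozygote; no phasing is attempted, so this over-calls).
#'   \item XLR: hemizygous or homozygous-alternate; a heterozygote also
#'     qualifies when `sex` is unknown.
#' }
#' Genes without mode data pass through unfiltered; unknown mode strings
#' trigger a warning and are treated as no data.
#'
#' @param variants Variant `data.frame` (typically after [filter_af()]).
#' @param modes Named list gene -> modes, e.g. from [gene_modes()].
#' @param sex Optional `"male"`/`"female"`; `NULL` means unknown.
#' @return Named list: gene -> variant `data.frame` of qualifying variants.
#'   Genes with no qualifying variant are absent.
#' @export
filter_inheritance <- function(variants, modes, sex = NULL) {
  if (is.null(variants) || !nrow(variants)) return(list())
  out <- list()
  for (g in sort(unique(as.character(variants$gene)))) {
    vg <- variants[variants$gene == g, , drop = FALSE]
    rownames(vg) <- NULL
    m <- modes[[g]]
    known_modes <- c("AD", "AR", "XLD", "XLR")
    unknown <- setdiff(m, known_modes)
    if (length(unknown)) {
      warning("unknown inheritance mode(s) for gene ", g, ": ",
              paste(unknown, collapse = ", "), " (treated as no data)")
    }
    m <- intersect(m, known_modes)
    if (is.null(modes[[g]]) || !length(m)) { # no usable mode data
      out[[g]] <- vg
      next
    }
    keep <- rep(FALSE, nrow(vg))
    if (any(c("AD", "XLD") %in% m)) keep <- rep(TRUE, nrow(vg))
    if ("AR" %in% m) {
      n_het <- length(unique(variant_key(vg)[vg$genotype == "het"]))
      if (any(vg$genotype == "hom_alt") || n_het >= 2L) {
        keep <- keep | vg$genotype %in% c("het", "hom_alt")
      }
    }
    if ("XLR" %in% m) {
      keep <- keep | vg$genotype %in% c("hemi", "hom_alt")
      if (is.null(sex)) keep <- keep | vg$genotype == "het"
    }
    if (any(keep)) out[[g]] <- vg[keep, , drop = FALSE]
  }
  out
}

#' Read a gene-disease association table
#'
#' Tab-delimited with header `gene`, `disease_id`, `inheritance`.
#' @param path File path.
#' @return `data.frame`.
#' @export
read_gene_disease <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "disease_id", "inheritance")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("gene-disease table missing column(s): ",
                         paste(miss, collapse = ", "))
  df
}

#' Read a gene metadata table
#'
#' Tab-delimited with header `gene` plus any of `lof_mechanism`,
#' `missense_constrained`, `truncating_mechanism`, `bs1_max_af`.
#' @param path File path.
#' @return `data.frame`.
#' @export
read_gene_meta <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"gene" %in% names(df)) stop("gene metadata table missing 'gene' column")
  df
}

#' Read a patient HPO term list
#'
#' Accepts a comma-separated string of term ids or a path to a file with one
#' id per line. Ids must match `HP:` followed by seven digits.
#'
#' @param x Character string or file path.
#' @return Character vector of unique term ids.
#' @export
read_patient_terms <- function(x) {
  terms <- if (length(x) == 1L && !grepl(",", x, fixed = TRUE) &&
               !grepl("^HP:", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, ",", fixed = TRUE), use.names = FALSE)
  }
  terms <- unique(trimws(terms))
  terms <- terms[nzchar(terms)]
  bad <- terms[!grepl("^HP:\\d{7}$", terms)]
  if (length(bad)) stop("malformed HPO term id(s): ", paste(bad, collapse = ", "))
  if (!length(terms)) stop("no HPO terms supplied")
  terms
}
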
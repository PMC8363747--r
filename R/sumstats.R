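#' @include AllClasses.R
NULL

#' Construct variant-trait association records
#'
#' Builds one or more rows of the canonical summary-statistics table used
#' throughout the package (one row per variant-trait association). Effects
#' for binary traits are stored on the log-odds scale; an odds ratio with
#' its confidence interval may be supplied instead of `beta`/`se` and is
#' converted with [orCiToBetaSe()].
#'
#' @param snp variant identifier(s).
#' @param effect_allele,other_allele allele labels (A/C/G/T or multi-base);
#'   effects are per copy of `effect_allele`.
#' @param eaf effect-allele frequency in \[0, 1\], or `NA`.
#' @param beta effect per effect-allele copy (SD units for quantitative
#'   traits, log-odds for binary traits).
#' @param se standard error of `beta` (> 0), or `NA`.
#' @param or,ci_low,ci_high odds ratio and confidence bounds, used when
#'   `beta`/`se` are not given.
#' @param level confidence level of `ci_low`/`ci_high`.
#' @param pval association p-value in (0, 1\], or `NA`.
#' @param n,n_cases,n_controls sample sizes (optional).
#' @param trait trait label.
#' @param trait_type `"quantitative"` or `"case_control"`.
#' @return a data.frame with the canonical columns `snp, effect_allele,
#'   other_allele, eaf, beta, se, pval, n, n_cases, n_controls, trait,
#'   trait_type`.
#' @examples
#' variantAssociation("rs3734626", "T", "C", eaf = 0.56,
#'                    beta = 0.325, se = 0.023, pval = 1.8e-45,
#'                    trait = "circulating_rspo3")
#' @export
variantAssociation <- function(snp, effect_allele, other_allele,
                               eaf = NA_real_, beta = NA_real_,
                               se = NA_real_, or = NA_real_,
                               ci_low = NA_real_, ci_high = NA_real_,
                               level = 0.95, pval = NA_real_, n = NA_real_,
                               n_cases = NA_real_, n_controls = NA_real_,
                               trait = "trait",
                               trait_type = c("quantitative",
                                              "case_control")) {
  trait_type <- match.arg(trait_type)
  x <- data.frame(snp = as.character(snp),
                  effect_allele = toupper(as.character(effect_allele)),
                  other_allele = toupper(as.character(other_allele)),
                  eaf = as.numeric(eaf), beta = as.numeric(beta),
                  se = as.numeric(se), pval = as.numeric(pval),
                  n = as.numeric(n), n_cases = as.numeric(n_cases),
                  n_controls = as.numeric(n_controls),
                  trait = as.character(trait), trait_type = trait_type,
                  stringsAsFactors = FALSE)
  useOR <- is.na(x$beta) & !is.na(or)
  if (any(useOR)) {
    conv <- orCiToBetaSe(or[useOR], ci_low[useOR], ci_high[useOR],
                         level = level)
    x$beta[useOR] <- conv$beta
    x$se[useOR] <- conv$se
  }
  validateSumstats(x)
  x
}

## Validate a canonical summary-statistics table; `lines` maps rows to
## source line numbers for error reporting.
validateSumstats <- function(x, lines = seq_len(nrow(x)) ) {
  missing_cols <- setdiff(.SUMSTATS_COLS, names(x))
  if (length(missing_cols))
    stop("summary-statistics table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bad <- character()
  at <- function(i) paste0("row/line ", lines[i])
  i <- which(!is.na(x$se) & x$se <= 0)
  if (length(i)) bad <- c(bad, paste0(at(i), ": se must be > 0"))
  i <- which(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1))
  if (length(i)) bad <- c(bad, paste0(at(i), ": eaf must lie in [0, 1]"))
  i <- which(x$effect_allele == x$other_allele)
  if (length(i)) bad <- c(bad, paste0(at(i), ": alleles must differ"))
  i <- which(!is.na(x$pval) & (x$pval <= 0 | x$pval > 1))
  if (length(i)) bad <- c(bad, paste0(at(i), ": pval must lie in (0, 1]"))
  i <- which(!x$trait_type %in% .TRAIT_TYPES)
  if (length(i)) bad <- c(bad, paste0(at(i), ": unknown trait_type"))
  if (length(bad))
    stop("invalid summary statistics:\n  ", paste(bad, collapse = "\n  "),
         call. = FALSE)
  invisible(x)
}

#' Convert an odds ratio with confidence interval to log-odds beta and SE
#'
#' Inverts the standard presentation of binary-trait effects:
#' `beta = ln(OR)` and `se = (ln(ci_high) - ln(ci_low)) / (2 z)`, where `z`
#' is the exact two-sided standard-normal quantile for `level`
#' (1.959964 for 0.95, never the rounded 1.96, so that
#' `exp(beta +/- z * se)` recovers the interval to machine precision).
#'
#' @param or odds ratio(s), > 0.
#' @param ci_low,ci_high confidence bounds with
#'   `0 < ci_low <= or <= ci_high`.
#' @param level confidence level of the interval (default 0.95).
#' @return list with numeric components `beta` and `se`.
#' @examples
#' orCiToBetaSe(0.95, 0.94, 0.96)  # fracture at any bone site
#' @export
orCiToBetaSe <- function(or, ci_low, ci_high, level = 0.95) {
  stopifnot(length(or) == length(ci_low), length(or) == length(ci_high))
  ok <- !is.na(or) & !is.na(ci_low) & !is.na(ci_high)
  if (any(ok & (or <= 0 | ci_low <= 0 | ci_high <= 0)))
    stop("odds ratios and confidence bounds must be positive",
         call. = FALSE)
  if (any(ok & ci_low == ci_high))
    stop("zero-width confidence interval: se is undefined", call. = FALSE)
  if (any(ok & (ci_low > or | or > ci_high)))
    stop("confidence bounds must satisfy ci_low <= or <= ci_high",
         call. = FALSE)
  z <- zQuantile(level)
  beta <- ifelse(ok, log(or), NA_real_)
  se <- ifelse(ok, (log(ci_high) - log(ci_low)) / (2 * z), NA_real_)
  list(beta = as.numeric(beta), se = as.numeric(se))
}

#' Default column-name map for summary-statistics files
#'
#' Maps the canonical column names onto the names used in a file. Override
#' entries to read files with other headers, e.g.
#' `sumstatsDialect(snp = "rsid", pval = "p")`.
#'
#' @param ... named overrides, `canonical = "file_column"`.
#' @return named character vector, canonical name -> file column name.
#' @export
sumstatsDialect <- function(...) {
  d <- c(snp = "snp", effect_allele = "effect_allele",
         other_allele = "other_allele", eaf = "eaf", beta = "beta",
         se = "se", or = "or", ci_low = "ci_low", ci_high = "ci_high",
         pval = "pval", n = "n", n_cases = "n_cases",
         n_controls = "n_controls", trait = "trait",
         trait_type = "trait_type")
  ov <- c(...)
  if (length(ov)) {
    unknown <- setdiff(names(ov), names(d))
    if (length(unknown))
      stop("unknown dialect entries: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    d[names(ov)] <- ov
  }
  d
}

#' Read GWAS summary statistics from a delimited text file
#'
#' Reads a whitespace- or tab-delimited file with a header row into the
#' canonical summary-statistics table. Rows that report an odds ratio with
#' confidence bounds instead of `beta`/`se` are converted with
#' [orCiToBetaSe()]. Malformed rows are reported with their line numbers.
#'
#' @param path file path.
#' @param dialect column-name map from [sumstatsDialect()].
#' @param level confidence level assumed for odds-ratio intervals.
#' @return data.frame with the canonical columns, one row per variant-trait
#'   association (zero rows for a header-only file).
#' @examples
#' tsv <- system.file("extdata", "table1_rspo3.tsv", package = "cisMR")
#' head(readSumstats(tsv))
#' @export
readSumstats <- function(path, dialect = sumstatsDialect(), level = 0.95) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = "",
                           stringsAsFactors = FALSE,
                           na.strings = c("NA", "", "."),
                           check.names = FALSE)
  mandatory <- c("snp", "effect_allele", "other_allele")
  miss <- mandatory[!dialect[mandatory] %in% names(raw)]
  if (length(miss))
    stop("missing mandatory columns in ", path, ": ",
         paste(dialect[miss], collapse = ", "), call. = FALSE)

  pick <- function(canon, default = NA) {
    col <- dialect[[canon]]
    if (col %in% names(raw)) raw[[col]] else rep(default, nrow(raw))
  }
  x <- data.frame(snp = as.character(pick("snp")),
                  effect_allele = toupper(as.character(pick("effect_allele"))),
                  other_allele = toupper(as.character(pick("other_allele"))),
                  eaf = as.numeric(pick("eaf", NA_real_)),
                  beta = as.numeric(pick("beta", NA_real_)),
                  se = as.numeric(pick("se", NA_real_)),
                  pval = as.numeric(pick("pval", NA_real_)),
                  n = as.numeric(pick("n", NA_real_)),
                  n_cases = as.numeric(pick("n_cases", NA_real_)),
                  n_controls = as.numeric(pick("n_controls", NA_real_)),
                  trait = as.character(pick("trait", "trait")),
                  trait_type = as.character(pick("trait_type",
                                                 "quantitative")),
                  stringsAsFactors = FALSE)
  if (nrow(x) == 0L) return(x)

  # printed p-values below the double denormal range (~5e-324) parse to 0;
  # keep them as the smallest representable positive value
  under <- !is.na(x$pval) & x$pval == 0
  x$pval[under] <- 5e-324

  # header is line 1, so data row i sits on line i + 1
  lines <- seq_len(nrow(x)) + 1L

  or <- as.numeric(pick("or", NA_real_))
  lo <- as.numeric(pick("ci_low", NA_real_))
  hi <- as.numeric(pick("ci_high", NA_real_))
  useOR <- is.na(x$beta) & !is.na(or)
  if (any(useOR)) {
    for (i in which(useOR)) {
      conv <- tryCatch(orCiToBetaSe(or[i], lo[i], hi[i], level = level),
                       error = function(e)
                         stop("line ", lines[i], ": ", conditionMessage(e),
                              call. = FALSE))
      x$beta[i] <- conv$beta
      x$se[i] <- conv$se
    }
  }
  validateSumstats(x, lines = lines)
  x
}

#' Write summary statistics to a tab-delimited file
#'
#' Writes the canonical `beta`/`se` representation (binary-trait effects on
#' the log-odds scale) so that [readSumstats()] recovers the table exactly.
#'
#' @param x canonical summary-statistics data.frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeSumstats <- function(x, path) {
  validateSumstats(x)
  out <- x[, .SUMSTATS_COLS]
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v)
    ifelse(is.na(v), NA, format(v, digits = 17, scientific = TRUE,
                                trim = TRUE)))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
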
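## Minimal polygenic-score construction from a dosage matrix and a weight
## table, mirroring standard score-file semantics.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Read a polygenic-score weight table
#'
#' Three whitespace- or tab-delimited columns: variant id, effect allele
#' (A/C/G/T), per-allele weight.  A header row is detected automatically.
#'
#' @param path File path.
#' @return Tibble with columns `variant_id`, `effect_allele`, `weight`.
#' @export
read_weight_table <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- !grepl("[-0-9.eE+]+\\s*$", first) ||
    grepl("weight|beta|effect_?size", first, ignore.case = TRUE)
  tab <- utils::read.table(path, header = has_header,
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 3) stop("weight table needs 3 columns")
  tab <- tab[, 1:3]
  names(tab) <- c("variant_id", "effect_allele", "weight")
  tab$effect_allele <- toupper(tab$effect_allele)
  if (anyDuplicated(tab$variant_id))
    stop("duplicated variant ids in weight table")
  if (any(!is.finite(tab$weight))) stop("non-finite weights")
  if (any(!tab$effect_allele %in% names(COMPLEMENT)))
    stop("effect alleles must be A/C/G/T")
  tibble::as_tibble(tab)
}

#' Read a PLINK-.raw-style dosage table
#'
#' Rectangular table with a header; metadata columns (FID, IID, PAT, MAT,
#' SEX, PHENOTYPE) are dropped except for the sample identifier.  Variant
#' columns are expected to be named `<variant_id>_<counted_allele>`;
#' entries are allele dosages in `[0, 2]` or missing.
#'
#' @param path File path.
#' @return List with `dosages` (persons x variants numeric matrix, rownames
#'   = sample ids), `counted_allele` (named by variant id).
#' @export
read_dosages <- function(path) {
  tab <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                    names(tab))
  ids <- if ("IID" %in% names(tab)) as.character(tab$IID)
         else as.character(seq_len(nrow(tab)))
  snp_cols <- setdiff(names(tab), meta)
  m <- regmatches(snp_cols, regexec("^(.*)_([ACGT])$", snp_cols))
  ok <- lengths(m) == 3
  if (!all(ok))
    stop("dosage columns without an _<allele> suffix: ",
         paste(snp_cols[!ok], collapse = ", "))
  vid <- vapply(m, `[`, "", 2)
  allele <- vapply(m, `[`, "", 3)
  D <- as.matrix(tab[, snp_cols, drop = FALSE])
  storage.mode(D) <- "double"
  if (any(D < 0 | D > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  dimnames(D) <- list(ids, vid)
  list(dosages = D, counted_allele = setNames(allele, vid))
}

#' Compute additive polygenic scores
#'
#' For each person, `score = sum_j w_j d_ij` over the variants shared
#' between the dosage matrix and the weight table.  Allele alignment: an
#' effect allele equal to the counted allele scores the dosage as-is; equal
#' to the variant's other allele, the dosage is reversed (`2 - d`); equal
#' to a complement of either, the variant is treated as strand-flipped and
#' resolved the same way.  Palindromic variants (allele pair A/T or C/G)
#' are strand-ambiguous and dropped with a count.  When the other allele is unknown, a complement
#' match cannot be disambiguated and is likewise dropped, and any remaining
#' mismatch is assumed to be the other allele (reversed).  A mismatch that
#' matches none of the four possibilities is reported per variant.
#'
#' @param dosages Persons x variants matrix (entries in `[0, 2]` or `NA`),
#'   or the list returned by [read_dosages()].
#' @param weights Weight table as from [read_weight_table()].
#' @param counted_allele Named character vector (by variant) of the allele
#'   the dosage counts; taken from `dosages` when that is a
#'   [read_dosages()] list.  If omitted entirely, alleles are assumed to
#'   match.
#' @param other_allele Optional named character vector of each variant's
#'   non-counted allele, enabling unambiguous strand-flip resolution.
#' @param missing_policy `"mean_impute"` replaces a missing dosage with
#'   that variant's sample mean; `"skip"` omits missing terms from the sum.
#' @return Numeric vector of scores (named by person) with attributes
#'   `n_variants_used` and `n_ambiguous_dropped`.
#' @export
#' @examples
#' d <- rbind(c(0, 1, 2))
#' colnames(d) <- c("v1", "v2", "v3")
#' w <- tibble::tibble(variant_id = colnames(d),
#'                     effect_allele = c("A", "C", "G"),
#'                     weight = c(0.5, -0.2, 0.1))
#' score_pgs(d, w)  # 0*0.5 + 1*-0.2 + 2*0.1 = 0
score_pgs <- function(dosages, weights,
                      missing_policy = c("mean_impute", "skip"),
                      counted_allele = NULL, other_allele = NULL) {
  missing_policy <- match.arg(missing_policy)
  if (is.list(dosages) && !is.matrix(dosages)) {
    counted_allele <- dosages$counted_allele
    dosages <- dosages$dosages
  }
  if (is.null(colnames(dosages))) stop("dosage matrix needs variant names")
  shared <- intersect(colnames(dosages), weights$variant_id)
  if (!length(shared))
    stop("no overlapping variants between dosages and weight table")
  W <- weights[match(shared, weights$variant_id), ]
  D <- dosages[, shared, drop = FALSE]
  w <- W$weight
  dropped <- 0L

  if (!is.null(counted_allele)) {
    ca <- unname(toupper(counted_allele[shared]))
    ea <- W$effect_allele
    oa <- if (!is.null(other_allele))
      unname(toupper(other_allele[shared])) else rep(NA_character_, length(ca))
    palindromic <- !is.na(oa) & oa == COMPLEMENT[ca]
    drop <- palindromic |
      (is.na(oa) & ea != ca & ea == COMPLEMENT[ca])
    keep_as_is <- !drop & ea == ca
    reverse <- !drop & !keep_as_is &
      ((!is.na(oa) & (ea == oa | ea == COMPLEMENT[oa])) |
         (is.na(oa) & ea != COMPLEMENT[ca]))
    flip_same <- !drop & !keep_as_is & !reverse & ea == COMPLEMENT[ca]
    unresolved <- !(drop | keep_as_is | reverse | flip_same)
    if (any(unresolved))
      stop("allele mismatch without a complement resolution for: ",
           paste(shared[unresolved], collapse = ", "))
    dropped <- sum(drop)
    if (any(reverse)) D[, reverse] <- 2 - D[, reverse]
    D <- D[, !drop, drop = FALSE]
    w <- w[!drop]
    if (!length(w)) stop("all shared variants dropped as palindromic")
  }

  if (anyNA(D)) {
    if (missing_policy == "mean_impute") {
      cm <- colMeans(D, na.rm = TRUE)
      idx <- which(is.na(D), arr.ind = TRUE)
      D[idx] <- cm[idx[, 2]]
    } else {
      D[is.na(D)] <- 0   # skip: missing terms contribute nothing
    }
  }
  out <- drop(D %*% w)
  attr(out, "n_variants_used") <- length(w)
  attr(out, "n_ambiguous_dropped") <- dropped
  out
}

#' Standardize scores to z-scores
#'
#' Centers and scales to mean 0, SD 1 (denominator `n - 1`).
#'
#' @param scores Numeric vector with at least 2 distinct finite values.
#' @return Z-scored vector.
#' @export
standardize_scores <- function(scores) {
  x <- as.numeric(scores)
  ok <- is.finite(x)
  if (length(unique(x[ok])) < 2)
    stop("cannot standardize a constant (or empty) score vector")
  (x - mean(x[ok])) / sd(x[ok])
}
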
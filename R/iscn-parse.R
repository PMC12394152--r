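# Chromosome labels in karyogram order; "mar" (marker of unknown origin) sorts last.
.chrom_levels <- c(as.character(1:22), "X", "Y")
.chrom_levels_mar <- c(.chrom_levels, "mar")
.acrocentrics <- c("13", "14", "15", "21", "22")

#' Sort chromosome labels in karyogram order
#'
#' Orders labels 1-22, then X, Y, with "mar" last. Unknown labels are dropped.
#'
#' @param x Character vector of chromosome labels.
#' @return `x` sorted in karyogram order, duplicates retained.
#' @export
#' @examples
#' chrom_sort(c("X", "9", "21", "2"))
chrom_sort <- function(x) {
  x[order(match(x, .chrom_levels_mar))]
}

# ---- condition constructors -------------------------------------------------

iscn_condition <- function(msg, class, token = NULL) {
  full <- if (is.null(token)) msg else sprintf("%s [token: '%s']", msg, token)
  stop(errorCondition(full, token = token,
                      class = c(class, "karyocohort_error")))
}

syntax_error <- function(msg, token = NULL) {
  iscn_condition(msg, "karyocohort_syntax_error", token)
}

unsupported_notation <- function(msg, token = NULL) {
  iscn_condition(msg, "karyocohort_unsupported_notation", token)
}

# ---- low-level constructors -------------------------------------------------

new_band <- function(chromosome, arm, designation) {
  list(chromosome = chromosome, arm = arm, designation = designation)
}

new_abnormality <- function(kind, chromosomes, breakpoints = list(),
                            raw_token = NA_character_) {
  structure(
    list(kind = kind, chromosomes = chromosomes,
         breakpoints = breakpoints, raw_token = raw_token),
    class = "iscn_abnormality"
  )
}

.numerical_kinds <- c("numerical_gain", "numerical_loss", "marker_gain")
.variant_kinds <- c("heterochromatin_variant", "satellite_variant",
                    "satellite_stalk_variant")

# regex fragments (applied to lower-cased tokens; anchored by callers)
.re_chr <- "(1[0-9]|2[0-2]|[1-9]|[xy])"
.re_band <- "([pq][0-9]+(?:\\.[0-9]+)?)"

.match <- function(text, pattern) {
  m <- regmatches(text, regexec(pattern, text, perl = TRUE))[[1]]
  if (length(m) == 0) NULL else m
}

.parse_band <- function(chromosome, band_str) {
  new_band(chromosome, substr(band_str, 1, 1), substring(band_str, 2))
}

# Heads that are legal ISCN but outside the supported subset.
.unsupported_head <- "^(fra\\(|ins\\(|r\\(|dic\\(|idic\\(|trc\\(|ish|arr|fis\\(|upd\\(|hsr|dmin|\\+?der|\\+[0-9xy]+,)"

# ---- token parser -----------------------------------------------------------

# Parses one comma-delimited abnormality token (whitespace already stripped,
# "psu dic" pre-normalised to "psudic"). Returns an iscn_abnormality.
parse_token <- function(tok) {
  if (!nzchar(tok)) syntax_error("empty abnormality token")
  tl <- tolower(tok)
  up <- function(x) toupper(x)

  # gain/loss of a whole chromosome, incl. +mar
  if (!is.null(m <- .match(tl, "^\\+mar$"))) {
    return(new_abnormality("marker_gain", "mar", raw_token = "+mar"))
  }
  if (!is.null(m <- .match(tl, paste0("^([+-])", .re_chr, "$")))) {
    kind <- if (m[2] == "+") "numerical_gain" else "numerical_loss"
    chr <- up(m[3])
    return(new_abnormality(kind, chr, raw_token = paste0(m[2], chr)))
  }

  # inversion, with or without printed breakpoints
  if (!is.null(m <- .match(tl, paste0("^inv\\(", .re_chr, "\\)(?:\\(",
                                      .re_band, .re_band, "\\))?$")))) {
    chr <- up(m[2])
    bps <- list()
    raw <- sprintf("inv(%s)", chr)
    if (nzchar(m[3])) {
      bps <- list(.parse_band(chr, m[3]), .parse_band(chr, m[4]))
      raw <- sprintf("inv(%s)(%s%s)", chr, m[3], m[4])
    }
    return(new_abnormality("inversion", chr, bps, raw))
  }

  # reciprocal translocation, two- or three-way
  if (!is.null(m <- .match(tl, "^t\\(([0-9xy;]+)\\)\\(([pq0-9.;]+)\\)$"))) {
    chrs <- strsplit(m[2], ";", fixed = TRUE)[[1]]
    bands <- strsplit(m[3], ";", fixed = TRUE)[[1]]
    if (!all(grepl(paste0("^", .re_chr, "$"), chrs, perl = TRUE)) ||
        !all(grepl(paste0("^", .re_band, "$"), bands, perl = TRUE))) {
      syntax_error("malformed translocation", tok)
    }
    if (length(chrs) != length(bands)) {
      syntax_error("translocation chromosome/breakpoint counts differ", tok)
    }
    if (length(chrs) > 3) {
      unsupported_notation("translocations with >3 chromosomes are not supported", tok)
    }
    if (length(chrs) < 2) syntax_error("translocation needs >=2 chromosomes", tok)
    chrs <- up(chrs)
    bps <- mapply(.parse_band, chrs, bands, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    raw <- sprintf("t(%s)(%s)", paste(chrs, collapse = ";"),
                   paste(bands, collapse = ";"))
    return(new_abnormality("reciprocal_translocation", chrs, bps, raw))
  }

  # Robertsonian translocation: rob(a;b)(q10;q10); der(a;b)(q10;q10) is the
  # equivalent whole-arm centric-fusion notation and classifies identically.
  rob_re <- paste0("^(rob|der)\\(", .re_chr, ";", .re_chr,
                   "\\)\\(([pq]10);([pq]10)\\)$")
  if (!is.null(m <- .match(tl, rob_re))) {
    chrs <- up(c(m[3], m[4]))
    bps <- list(.parse_band(chrs[1], m[5]), .parse_band(chrs[2], m[6]))
    raw <- sprintf("%s(%s;%s)(%s;%s)", m[2], chrs[1], chrs[2], m[5], m[6])
    return(new_abnormality("robertsonian", chrs, bps, raw))
  }

  # derivative chromosome, optionally with an embedded translocation
  if (!is.null(m <- .match(tl, paste0("^der\\(", .re_chr, "\\)(.*)$")))) {
    chr <- up(m[2])
    rest <- m[3]
    if (!nzchar(rest)) {
      return(new_abnormality("derivative", chr, raw_token = sprintf("der(%s)", chr)))
    }
    inner <- parse_token(rest)
    if (inner$kind != "reciprocal_translocation") {
      syntax_error("derivative detail must be a translocation", tok)
    }
    chrs <- unique(c(chr, inner$chromosomes))
    raw <- sprintf("der(%s)%s", chr, inner$raw_token)
    return(new_abnormality("derivative", chrs, inner$breakpoints, raw))
  }

  # deletion: one band = terminal, two bands = interstitial
  if (!is.null(m <- .match(tl, paste0("^del\\(", .re_chr, "\\)\\(", .re_band,
                                      "(?:", .re_band, ")?\\)$")))) {
    chr <- up(m[2])
    bands <- c(m[3], m[4])
    bands <- bands[nzchar(bands)]
    bps <- lapply(bands, .parse_band, chromosome = chr)
    raw <- sprintf("del(%s)(%s)", chr, paste(bands, collapse = ""))
    return(new_abnormality("deletion", chr, bps, raw))
  }

  # duplication: always two bands delimiting the duplicated segment
  if (!is.null(m <- .match(tl, paste0("^dup\\(", .re_chr, "\\)\\(", .re_band,
                                      .re_band, "\\)$")))) {
    chr <- up(m[2])
    bps <- list(.parse_band(chr, m[3]), .parse_band(chr, m[4]))
    raw <- sprintf("dup(%s)(%s%s)", chr, m[3], m[4])
    return(new_abnormality("duplication", chr, bps, raw))
  }

  # isochromosome: whole-arm only, i(c)(p10) or i(c)(q10)
  if (!is.null(m <- .match(tl, paste0("^i\\(", .re_chr, "\\)\\(([pq]10)\\)$")))) {
    chr <- up(m[2])
    return(new_abnormality("isochromosome", chr,
                           list(.parse_band(chr, m[3])),
                           sprintf("i(%s)(%s)", chr, m[3])))
  }

  # pseudodicentric: one or two listed chromosomes
  if (!is.null(m <- .match(tl, "^psudic\\(([0-9xy;]+)\\)\\(([pq0-9.;]+)\\)$"))) {
    chrs <- strsplit(m[2], ";", fixed = TRUE)[[1]]
    bands <- strsplit(m[3], ";", fixed = TRUE)[[1]]
    if (!all(grepl(paste0("^", .re_chr, "$"), chrs, perl = TRUE)) ||
        !all(grepl(paste0("^", .re_band, "$"), bands, perl = TRUE)) ||
        length(chrs) != length(bands) || length(chrs) > 2) {
      syntax_error("malformed psu dic token", tok)
    }
    chrs <- up(chrs)
    bps <- mapply(.parse_band, chrs, bands, SIMPLIFY = FALSE, USE.NAMES = FALSE)
    raw <- sprintf("psu dic(%s)(%s)", paste(chrs, collapse = ";"),
                   paste(bands, collapse = ";"))
    return(new_abnormality("psu_dic", unique(chrs), bps, raw))
  }

  # additional material of unknown origin
  if (!is.null(m <- .match(tl, paste0("^add\\(", .re_chr, "\\)\\(", .re_band, "\\)$")))) {
    chr <- up(m[2])
    return(new_abnormality("addition", chr, list(.parse_band(chr, m[3])),
                           sprintf("add(%s)(%s)", chr, m[3])))
  }

  # length polymorphisms: heterochromatin (qh+/-), satellite (ps+),
  # satellite stalk (pstk+)
  if (!is.null(m <- .match(tl, paste0("^", .re_chr, "(qh|ps|pstk)([+-])$")))) {
    chr <- up(m[2])
    kind <- switch(m[3],
                   qh = "heterochromatin_variant",
                   ps = "satellite_variant",
                   pstk = "satellite_stalk_variant")
    if (m[3] == "qh" && !chr %in% c("1", "9", "16", "Y")) {
      syntax_error("heterochromatin length variants are recognised on 1, 9, 16 and Y", tok)
    }
    if (m[3] != "qh") {
      if (!chr %in% .acrocentrics) {
        syntax_error("satellite/stalk variants occur on acrocentric chromosomes", tok)
      }
      if (m[4] != "+") syntax_error("satellite/stalk variants are gains (+)", tok)
    }
    return(new_abnormality(kind, chr, raw_token = paste0(chr, m[3], m[4])))
  }

  if (grepl(.unsupported_head, tl, perl = TRUE)) {
    unsupported_notation("valid ISCN outside the supported subset", tok)
  }
  syntax_error("unrecognised abnormality token", tok)
}

# ---- clone parser -----------------------------------------------------------

# Numerical abnormalities implied by the sex-chromosome complement: 45,X is a
# loss of one X, 47,XXY a gain of one X, 47,XYY a gain of one Y, etc. Skipped
# when any structural token already involves a sex chromosome (e.g.
# 46,X,i(X)(q10)) or when the complement is masked ("N").
implied_sex_abnormalities <- function(sex, abnormalities) {
  if (grepl("N", sex, fixed = TRUE)) return(list())
  if (sex %in% c("XX", "XY")) return(list())
  involved <- unique(unlist(lapply(abnormalities, `[[`, "chromosomes")))
  if (any(c("X", "Y") %in% involved)) return(list())
  nX <- lengths(regmatches(sex, gregexpr("X", sex)))
  nY <- lengths(regmatches(sex, gregexpr("Y", sex)))
  refX <- if (nY > 0) 1L else 2L
  refY <- if (nY > 0) 1L else 0L
  out <- list()
  add <- function(kind, chr, times) {
    lapply(seq_len(times), function(i) new_abnormality(kind, chr))
  }
  out <- c(out,
           if (nX > refX) add("numerical_gain", "X", nX - refX),
           if (nX < refX) add("numerical_loss", "X", refX - nX),
           if (nY > refY) add("numerical_gain", "Y", nY - refY),
           if (nY < refY) add("numerical_loss", "Y", refY - nY))
  out
}

# Modal-number arithmetic is enforced only for clones whose abnormalities are
# purely numerical; structural tokens (iso, rob, der, ...) shift chromosome
# counts in notation-dependent ways that the band-level model does not track.
check_modal_consistency <- function(modal, sex, abnormalities, clone_text) {
  kinds <- vapply(abnormalities, `[[`, character(1), "kind")
  if (length(kinds) > 0 && !all(kinds %in% .numerical_kinds)) return(invisible())
  explicit <- abnormalities[!vapply(abnormalities, function(a) is.na(a$raw_token), logical(1))]
  delta <- sum(vapply(explicit, function(a) {
    if (a$kind == "numerical_loss") -1L else 1L
  }, integer(1)))
  expected <- 44L + nchar(sex) + delta
  if (modal != expected) {
    syntax_error(sprintf(
      "modal number %d inconsistent with sex designation and numerical tokens (expected %d)",
      modal, expected), clone_text)
  }
  invisible()
}

parse_clone <- function(clone_text) {
  cs <- clone_text
  cell_count <- NA_integer_
  m <- .match(cs, "^(.*?)\\[([0-9]+)\\]$")
  if (!is.null(m)) {
    cs <- m[2]
    cell_count <- suppressWarnings(as.integer(m[3]))
    if (is.na(cell_count) || cell_count < 1L) {
      syntax_error("cell count must be a positive integer", clone_text)
    }
  }
  fields <- strsplit(cs, ",", fixed = TRUE)[[1]]
  if (length(fields) < 2 || any(!nzchar(fields))) {
    syntax_error("clone must be 'modal,sex[,abnormalities...]'", clone_text)
  }
  if (!grepl("^[0-9]+$", fields[1])) {
    syntax_error("modal number must be an integer", fields[1])
  }
  modal <- as.integer(fields[1])
  sex <- toupper(fields[2])
  if (!grepl("^[XYN]+$", sex)) {
    syntax_error("sex designation must be a string over X, Y, N", fields[2])
  }
  abns <- lapply(fields[-(1:2)], parse_token)

  if (modal == 69L) {
    # triploidy: whole-genome gain, reported with a three-letter sex field
    if (length(abns) > 0) {
      unsupported_notation("triploid clones with additional abnormalities are not supported",
                           clone_text)
    }
    if (nchar(sex) != 3) {
      syntax_error("modal number 69 requires a three-letter sex designation", clone_text)
    }
  } else {
    abns <- c(implied_sex_abnormalities(sex, abns), abns)
    check_modal_consistency(modal, sex, abns, clone_text)
  }

  list(modal_number = modal, sex_designation = sex,
       abnormalities = abns, cell_count = cell_count)
}

# ---- karyotype parser -------------------------------------------------------

#' Parse an ISCN karyotype string
#'
#' Parses the subset of ISCN 2016 nomenclature covering the karyotype classes
#' seen in constitutional prenatal diagnostics: ploidy + sex header,
#' "/"-separated clones with optional `[n]` cell counts and optional
#' `mos `/`chi ` prefixes, whole-chromosome gains/losses (incl. `+mar`),
#' inversions, reciprocal (2- and 3-way) translocations, Robertsonian
#' translocations (`rob` or whole-arm `der` notation), deletions,
#' duplications, isochromosomes, `psu dic`, derivatives with embedded
#' translocation detail, `add`, and the heterochromatin/satellite/stalk
#' length-variant tokens (`9qh+`, `Yqh-`, `15ps+`, `22pstk+`, ...).
#'
#' Whitespace and case are normalised (`"inv (9)"` parses like `"inv(9)"`);
#' the masked sex designation `"XN"` is accepted. Sex-chromosome aneuploidies
#' written in the header (`45,X`, `47,XXY`) yield implied numerical
#' abnormalities. Malformed strings raise a condition of class
#' `karyocohort_syntax_error`; recognisable ISCN outside the subset (e.g.
#' `fra`, `ins`, rings) raises `karyocohort_unsupported_notation`. A modal
#' number contradicting the token arithmetic of a purely numerical clone
#' (e.g. `"46,XX,+21"`) is rejected.
#'
#' @param text A single ISCN karyotype string.
#' @return An object of class `iscn_karyotype`: a list with `clones` (each a
#'   list with `modal_number`, `sex_designation`, `abnormalities`,
#'   `cell_count`), `mos_prefix`, `chi_prefix` and `raw`.
#' @seealso [format_karyotype()], [classify()]
#' @export
#' @examples
#' parse_karyotype("46,XX")
#' parse_karyotype("mos 45,X[12]/46,XX[18]")
#' parse_karyotype("46,XN,inv(9)(p12q13)")
#' parse_karyotype("45,XY,rob(13;14)(q10;q10)")
parse_karyotype <- function(text) {
  if (!is.character(text) || length(text) != 1 || is.na(text)) {
    syntax_error("karyotype must be a single character string")
  }
  raw <- trimws(text)
  if (!nzchar(raw)) syntax_error("empty karyotype string")
  s <- gsub("\\s+", " ", raw)
  mos <- grepl("^mos ", s, ignore.case = TRUE)
  chi <- grepl("^chi ", s, ignore.case = TRUE)
  body <- sub("^(mos|chi) ", "", s, ignore.case = TRUE)
  body <- gsub("psu ?dic", "psudic", body, ignore.case = TRUE)
  body <- gsub(" ", "", body, fixed = TRUE)
  if (!nzchar(body)) syntax_error("no clones in karyotype string", raw)
  clone_strs <- strsplit(body, "/", fixed = TRUE)[[1]]
  if (length(clone_strs) == 0 || any(!nzchar(clone_strs))) {
    syntax_error("empty clone between '/' separators", raw)
  }
  clones <- lapply(clone_strs, parse_clone)
  if (mos && length(clones) < 2) {
    syntax_error("'mos' prefix requires at least two clones", raw)
  }
  structure(list(clones = clones, mos_prefix = mos, chi_prefix = chi, raw = raw),
            class = "iscn_karyotype")
}

# ---- signatures and equality ------------------------------------------------

abn_signature <- function(a) {
  bp <- vapply(a$breakpoints, function(b) paste0(b$chromosome, b$arm, b$designation),
               character(1))
  paste(a$kind, paste(a$chromosomes, collapse = ";"),
        paste(bp, collapse = ";"), sep = "|")
}

# Genetic identity of a clone: modal number, sex complement and abnormality
# set. Cell counts are deliberately excluded.
clone_signature <- function(clone) {
  sigs <- sort(vapply(clone$abnormalities, abn_signature, character(1)))
  paste(clone$modal_number, clone$sex_designation,
        paste(sigs, collapse = "&"), sep = "~")
}

#' Structural equality of two parsed karyotypes
#'
#' Compares clone structure (modal numbers, sex designations, cell counts and
#' typed abnormalities) while ignoring the raw input strings, so that
#' differently spaced or cased spellings of the same karyotype compare equal.
#'
#' @param a,b `iscn_karyotype` objects.
#' @return `TRUE` or `FALSE`.
#' @export
karyotype_equal <- function(a, b) {
  strip <- function(k) {
    list(k$mos_prefix, k$chi_prefix,
         lapply(k$clones, function(cl) {
           list(cl$modal_number, cl$sex_designation, cl$cell_count,
                lapply(cl$abnormalities,
                       function(ab) ab[c("kind", "chromosomes", "breakpoints")]))
         }))
  }
  identical(strip(a), strip(b))
}

#' @export
print.iscn_karyotype <- function(x, ...) {
  cat("<iscn_karyotype> ", format_karyotype(x), "\n", sep = "")
  for (i in seq_along(x$clones)) {
    cl <- x$clones[[i]]
    kinds <- vapply(cl$abnormalities, `[[`, character(1), "kind")
    cat(sprintf("  clone %d: modal %d, sex %s%s%s\n", i, cl$modal_number,
                cl$sex_designation,
                if (!is.na(cl$cell_count)) sprintf(", %d cells", cl$cell_count) else "",
                if (length(kinds)) paste0(" [", paste(kinds, collapse = ", "), "]") else ""))
  }
  invisible(x)
}
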
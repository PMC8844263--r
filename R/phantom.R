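#' Reference adult phantom organ masses
#'
#' Organ masses (g) of the hermaphroditic 70-kg reference adult used for
#' normalization, surrogate mass-weighting and the sphere self-dose model.
#' The mass list follows the classic reference-adult anatomical model and
#' is extended with four glands with assigned standard masses: parotid
#' glands 25 g, submandibular glands 12.5 g, sublingual glands 12.5 g,
#' lacrimal glands 5 g.
#'
#' @return A tibble with columns `organ` and `mass_g`.
#' @examples
#' reference_phantom()
#' @export
reference_phantom <- function() {
  tibble::tribble(
    ~organ,                    ~mass_g,
    "adrenals",                  16.3,
    "brain",                   1420,
    "breasts",                  351,
    "gallbladder_wall",          10.5,
    "gallbladder_content",       55.7,
    "lli_wall",                 167,
    "lli_content",               75,
    "small_intestine",          677,
    "stomach_wall",             158,
    "stomach_content",          260,
    "uli_wall",                 220,
    "uli_content",              135,
    "heart_wall",               316,
    "heart_content",            454,
    "kidneys",                  299,
    "liver",                   1910,
    "lungs",                   1000,
    "muscle",                 28000,
    "ovaries",                    8.71,
    "pancreas",                  94.3,
    "red_marrow",              1120,
    "cortical_bone",           4000,
    "trabecular_bone",         1000,
    "osteogenic_cells",         120,
    "skin",                    3010,
    "spleen",                   183,
    "testes",                    39.1,
    "thymus",                    20.9,
    "thyroid",                   20.7,
    "urinary_bladder_wall",      47.6,
    "urinary_bladder_content",  211,
    "uterus",                    79,
    "parotid_glands",            25,
    "submandibular_glands",      12.5,
    "sublingual_glands",         12.5,
    "lacrimal_glands",            5,
    "total_body",             73700
  )
}

#' The four added glands handled by the sphere self-dose model
#' @return Character vector of organ names.
#' @export
gland_organs <- function() {
  c("parotid_glands", "submandibular_glands", "sublingual_glands",
    "lacrimal_glands")
}

#' ICRP-60 tissue weighting factors
#'
#' The 12 explicitly weighted tissues plus the 0.05 remainder. Weights sum
#' to 1. The remainder tissue list (used by [effective_dose()]) is attached
#' as attribute `"remainder_tissues"`: adrenals, brain, small intestine,
#' kidneys, muscle, pancreas, spleen, thymus and uterus (upper and lower
#' large intestine are consumed by the colon surrogate).
#'
#' @return A tibble with columns `tissue` and `w`.
#' @export
icrp60_weights <- function() {
  w <- tibble::tribble(
    ~tissue,          ~w,
    "gonads",         0.20,
    "red_marrow",     0.12,
    "colon",          0.12,
    "lungs",          0.12,
    "stomach_wall",   0.12,
    "urinary_bladder_wall", 0.05,
    "breasts",        0.05,
    "liver",          0.05,
    "esophagus",      0.05,
    "thyroid",        0.05,
    "skin",           0.01,
    "osteogenic_cells", 0.01,
    "remainder",      0.05
  )
  attr(w, "remainder_tissues") <- c(
    "adrenals", "brain", "small_intestine", "kidneys", "muscle",
    "pancreas", "spleen", "thymus", "uterus")
  w
}

#' Read / write a phantom definition
#'
#' Plain CSV with columns `organ,mass_g`; `#`-prefixed lines are comments.
#'
#' @param path File path.
#' @param phantom A phantom tibble as from [reference_phantom()].
#' @return `read_phantom()` returns the phantom tibble.
#' @export
read_phantom <- function(path) {
  x <- readr::read_csv(path, comment = "#", show_col_types = FALSE)
  stopifnot(all(c("organ", "mass_g") %in% names(x)))
  if (any(x$mass_g <= 0)) stop("phantom masses must be positive")
  tibble::as_tibble(x[, c("organ", "mass_g")])
}

#' @rdname read_phantom
#' @export
write_phantom <- function(phantom, path) {
  readr::write_csv(phantom, path)
  invisible(path)
}

.phantom_mass <- function(phantom, organ) {
  i <- match(organ, phantom$organ)
  if (anyNA(i)) {
    stop("organ(s) not in phantom: ", paste(organ[is.na(i)], collapse = ", "),
         call. = FALSE)
  }
  phantom$mass_g[i]
}
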
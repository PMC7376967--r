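#' Phantom label codes
#'
#' Integer label codes used in the voxel phantom. Label 0 is background
#' (outside the head) and is excluded from the conductive domain.
#'
#' @return Named integer vector mapping tissue-class names to label ids.
#' @export
#' @examples
#' phantom_labels()["hippocampus"]
phantom_labels <- function() {
  c(background = 0L, dura = 1L, csf = 2L, gray = 3L, white = 4L,
    ventricle = 5L, hippocampus = 6L, svz = 7L)
}

#' Parenchymal label codes
#'
#' Labels counted as brain parenchyma for safety and ROI purposes:
#' gray matter, white matter, hippocampus and the SVZ shell. Dura and
#' CSF (shell and ventricular) are excluded.
#'
#' @return Integer vector of label ids.
#' @export
parenchyma_labels <- function() {
  unname(phantom_labels()[c("gray", "white", "hippocampus", "svz")])
}

#' Default tissue-property table
#'
#' Quasi-static electrical properties at the 40 Hz stimulation frequency.
#' Conductivities follow the values in routine use for low-frequency
#' volume-conductor models of transcranial/epidural stimulation
#' (CSF 1.79, gray matter 0.276, white matter 0.126, dura 0.367 S/m);
#' relative permittivities are representative low-frequency dispersion
#' values and enter only the quasi-static validity report, never the
#' ohmic solve. All values are overridable via a user CSV.
#'
#' @param frequency_hz Frequency at which the values apply (Hz).
#' @return data.frame with columns `label_id`, `name`, `sigma_S_per_m`,
#'   `eps_r`, `frequency_Hz`.
#' @export
#' @examples
#' default_tissue_table()
default_tissue_table <- function(frequency_hz = 40) {
  lab <- phantom_labels()
  tab <- data.frame(
    label_id = unname(lab[c("dura", "csf", "gray", "white",
                            "ventricle", "hippocampus", "svz")]),
    name = c("dura", "csf_shell", "gray_matter", "white_matter",
             "ventricular_csf", "hippocampus", "svz_shell"),
    sigma_S_per_m = c(0.367, 1.79, 0.276, 0.126, 1.79, 0.276, 0.276),
    eps_r = c(1e6, 109, 4.07e7, 2.76e7, 109, 4.07e7, 4.07e7),
    frequency_Hz = frequency_hz,
    stringsAsFactors = FALSE
  )
  validate_tissue_table(tab)
  tab
}

#' Validate a tissue-property table
#'
#' Checks positivity of conductivities, permittivities >= 1, unique label
#' ids, and the conductivity ordering CSF > gray matter > white matter that
#' the layered head model relies on.
#'
#' @param tab data.frame as returned by [default_tissue_table()].
#' @param check_ordering Enforce the CSF > gray > white ordering. Disable
#'   for phantom property tables whose thin shells carry effective
#'   (sheet-conductance-scaled) conductivities.
#' @return The table, invisibly, if valid; otherwise an error.
#' @export
validate_tissue_table <- function(tab, check_ordering = TRUE) {
  stopifnot(is.data.frame(tab))
  req <- c("label_id", "name", "sigma_S_per_m", "eps_r", "frequency_Hz")
  missing_cols <- setdiff(req, names(tab))
  if (length(missing_cols) > 0)
    stop("tissue table missing columns: ", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(tab$label_id))
    stop("tissue table has duplicated label_id values")
  if (any(tab$sigma_S_per_m <= 0)) stop("all conductivities must be > 0")
  if (any(tab$eps_r < 1)) stop("all relative permittivities must be >= 1")
  if (any(tab$frequency_Hz <= 0)) stop("frequency must be > 0")
  if (check_ordering) {
    sig <- function(nm) tab$sigma_S_per_m[match(nm, tab$name)]
    s_csf <- sig("csf_shell"); s_gm <- sig("gray_matter")
    s_wm <- sig("white_matter")
    if (!any(is.na(c(s_csf, s_gm, s_wm))) && !(s_csf > s_gm && s_gm > s_wm))
      stop("conductivity ordering violated: require CSF > gray matter > white matter")
  }
  invisible(tab)
}

#' Read a tissue-property table from CSV
#'
#' @param path CSV file with columns
#'   `label_id,name,sigma_S_per_m,eps_r,frequency_Hz`.
#' @return Validated data.frame.
#' @export
read_tissue_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_tissue_table(tab)
  tab
}

#' Effective conductivity of a sub-voxel conductive sheet
#'
#' When a thin layer (e.g. the 43 um CSF film under the dura) is thinner
#' than the voxel size, representing it as one full voxel would inflate its
#' tangential sheet conductance. Scaling the conductivity by
#' `true_thickness / voxel_size` preserves the sheet conductance
#' sigma * t of the physical layer.
#'
#' @param sigma Conductivity of the physical layer (S/m).
#' @param true_thickness Physical layer thickness (um).
#' @param voxel_size Voxel edge length (um).
#' @return Effective conductivity (S/m) for a 1-voxel-thick shell.
#' @export
#' @examples
#' effective_shell_conductivity(1.79, 43, 100) # 0.7697
effective_shell_conductivity <- function(sigma, true_thickness, voxel_size) {
  stopifnot(sigma > 0, true_thickness > 0, voxel_size > 0)
  if (true_thickness > voxel_size)
    stop("true_thickness exceeds voxel_size; use a multi-voxel shell instead of scaling")
  sigma * true_thickness / voxel_size
}

#' Quasi-static validity check
#'
#' Ratio of displacement to ohmic current magnitude per tissue,
#' r = 2 pi f eps0 eps_r / sigma. Tissues with r >= 0.1 are flagged:
#' for them the purely ohmic solve is a questionable approximation.
#'
#' @param tab Tissue-property table.
#' @param f Frequency in Hz.
#' @return data.frame with per-tissue `ratio` and logical `flagged`.
#' @export
#' @examples
#' check_quasistatic(default_tissue_table(), 40)
check_quasistatic <- function(tab, f) {
  stopifnot(f >= 0)
  validate_tissue_table(tab)
  eps0 <- 8.854e-12
  ratio <- 2 * pi * f * eps0 * tab$eps_r / tab$sigma_S_per_m
  data.frame(name = tab$name, label_id = tab$label_id,
             ratio = ratio, flagged = ratio >= 0.1,
             stringsAsFactors = FALSE)
}
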
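# Standard base geometries in the standard reference frame for nucleic acid
# bases (ring atoms only, coordinates in Angstrom, base plane = xy).
# Values follow the published standard reference frame convention for the
# canonical bases; they are versioned package constants (v1). Only ring atoms
# enter frame fitting (C1' and exocyclic substituents excluded), so modified
# cytosines reuse the cytosine ring definition and yield frames directly
# comparable to unmodified C.

.std_base_coords <- list(
  A = matrix(c(
    -1.291, 4.498, 0.000,   # N9
     0.024, 4.897, 0.000,   # C8
     0.877, 3.902, 0.000,   # N7
     0.071, 2.771, 0.000,   # C5
     0.369, 1.398, 0.000,   # C6
    -0.668, 0.532, 0.000,   # N1
    -1.912, 1.023, 0.000,   # C2
    -2.320, 2.290, 0.000,   # N3
    -1.267, 3.124, 0.000),  # C4
    ncol = 3, byrow = TRUE,
    dimnames = list(c("N9","C8","N7","C5","C6","N1","C2","N3","C4"),
                    c("x","y","z"))),
  G = matrix(c(
    -1.289, 4.551, 0.000,
     0.023, 4.962, 0.000,
     0.870, 3.969, 0.000,
     0.071, 2.833, 0.000,
     0.424, 1.460, 0.000,
    -0.700, 0.641, 0.000,
    -1.999, 1.087, 0.000,
    -2.342, 2.364, 0.000,
    -1.265, 3.177, 0.000),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("N9","C8","N7","C5","C6","N1","C2","N3","C4"),
                    c("x","y","z"))),
  C = matrix(c(
    -1.285, 4.542, 0.000,   # N1
    -1.472, 3.158, 0.000,   # C2
    -0.391, 2.344, 0.000,   # N3
     0.837, 2.868, 0.000,   # C4
     1.056, 4.275, 0.000,   # C5
    -0.023, 5.068, 0.000),  # C6
    ncol = 3, byrow = TRUE,
    dimnames = list(c("N1","C2","N3","C4","C5","C6"), c("x","y","z"))),
  T = matrix(c(
    -1.284, 4.500, 0.000,
    -1.462, 3.135, 0.000,
    -0.298, 2.407, 0.000,
     0.994, 2.897, 0.000,
     1.106, 4.338, 0.000,
    -0.024, 5.057, 0.000),
    ncol = 3, byrow = TRUE,
    dimnames = list(c("N1","C2","N3","C4","C5","C6"), c("x","y","z")))
)

#' Standard base geometry (ring atoms)
#'
#' Ring-atom coordinates of a base in its standard reference frame. Modified
#' cytosines (`5mC`, `5hmC`, `5fC`, `5caC`) reuse the cytosine ring
#' definition so that fitted frames are comparable across conditions.
#'
#' @param base_type One of `A`, `C`, `G`, `T`, `5mC`, `5hmC`, `5fC`, `5caC`.
#' @return Numeric matrix (atoms x 3) with atom-name rownames.
#' @export
#' @examples
#' standard_base_geometry("5fC")
standard_base_geometry <- function(base_type) {
  base_type <- as.character(base_type)
  if (base_type %in% MOD_TYPES) base_type <- "C"
  if (!base_type %in% names(.std_base_coords)) {
    stop("unknown base type '", base_type, "'", call. = FALSE)
  }
  .std_base_coords[[base_type]]
}
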
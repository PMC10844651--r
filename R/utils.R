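#' @keywords internal
"_PACKAGE"

# Canonical upper-body joint order used throughout the package.
# Indices into the BODY_25 keypoint layout (0-based) are given alongside.
DYADSYNC_JOINTS <- c(
  "neck",       # BODY_25 index 1
  "r_shoulder", # 2
  "l_shoulder", # 5
  "r_elbow",    # 3
  "l_elbow",    # 6
  "r_hand",     # 4 (wrist)
  "l_hand"      # 7 (wrist)
)

BODY25_UPPER_IDX <- c(1L, 2L, 5L, 3L, 6L, 4L, 7L)

#' Canonical joint names
#'
#' The seven upper-body joints tracked by this package, in the fixed order
#' used by every array-valued structure: neck, right shoulder, left shoulder,
#' right elbow, left elbow, right hand (wrist), left hand (wrist).
#'
#' @return Character vector of length 7.
#' @export
dyad_joints <- function() DYADSYNC_JOINTS

# Derive a reproducible child seed from a base seed and an offset,
# keeping the result a valid 32-bit integer.
child_seed <- function(seed, offset) {
  s <- (as.double(seed) * 1000003 + as.double(offset)) %% 2147483647
  as.integer(s)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_dyadsync <- function(...) stop(..., call. = FALSE)
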
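# Fixed domain constants: the AU intensity set, facial regions, the 64-channel
# EEG montage and the default 62-channel analysis whitelist, electrode groups,
# and the analysis time zones.

#' Default facial action-unit set (17 intensity AUs)
#'
#' The 17 FACS action units whose frame-wise intensities form the AU input
#' matrix: inner/outer brow raiser (AU1/2), brow lowerer (AU4), upper lid
#' raiser (AU5), cheek raiser (AU6), lid tightener (AU7), nose wrinkler (AU9),
#' upper lip raiser (AU10), lip corner puller (AU12), dimpler (AU14), lip
#' corner depressor (AU15), chin raiser (AU17), lip stretcher (AU20), lip
#' tightener (AU23), lips part (AU25), jaw drop (AU26), and blink (AU45).
#' Head-pose AUs and the pucker/bite/suck/jaw transients are excluded.
#'
#' @return character vector of 17 zero-padded AU identifiers ("AU01", ...)
#' @export
au_default_names <- function() {
  sprintf("AU%02d", c(1, 2, 4, 5, 6, 7, 9, 10, 12, 14, 15, 17, 20, 23, 25, 26, 45))
}

#' Upper/lower face region of each action unit
#'
#' Brow, lid and cheek AUs (1, 2, 4, 5, 6, 7, 45) form the upper-face region;
#' the remaining nose/mouth/jaw AUs form the lower-face region.
#'
#' @param au_names AU identifiers, default [au_default_names()]
#' @return named character vector mapping each AU to "upper" or "lower"
#' @export
au_region_map <- function(au_names = au_default_names()) {
  upper <- sprintf("AU%02d", c(1, 2, 4, 5, 6, 7, 45))
  stats::setNames(ifelse(au_names %in% upper, "upper", "lower"), au_names)
}

#' The 64-channel recording montage
#'
#' 60 scalp sites of the extended 10-20 system plus four periocular channels
#' (two lateral to the eyes, two above/below the left eye).
#'
#' @return character vector of 64 channel labels
#' @export
montage_64 <- function() {
  c(scalp_60(), "HEOL", "HEOR", "VEOU", "VEOL")
}

scalp_60 <- function() {
  c("FP1", "FPZ", "FP2", "AF3", "AF4",
    "F7", "F5", "F3", "F1", "FZ", "F2", "F4", "F6", "F8",
    "FT7", "FC5", "FC3", "FC1", "FCZ", "FC2", "FC4", "FC6", "FT8",
    "T7", "C5", "C3", "C1", "CZ", "C2", "C4", "C6", "T8",
    "TP7", "CP5", "CP3", "CP1", "CPZ", "CP2", "CP4", "CP6", "TP8",
    "P7", "P5", "P3", "P1", "PZ", "P2", "P4", "P6", "P8",
    "PO7", "PO5", "PO3", "POZ", "PO4", "PO6", "PO8",
    "O1", "OZ", "O2")
}

#' Default 62-channel analysis whitelist
#'
#' The 60 scalp channels plus the two periocular channels lateral to the eyes.
#' Row order of EEG trial matrices follows this vector.
#'
#' @return character vector of 62 channel labels
#' @export
channel_whitelist_62 <- function() {
  c(scalp_60(), "HEOL", "HEOR")
}

#' Default electrode grouping for attribution statistics
#'
#' Neighbourhood groups of the 10-20 montage: anterior-frontal (AF), lateral
#' frontal (LF), central (C), the frontopolar and temporal single sites
#' (FP1, FP2, T7, T8), and "other" for the rest.
#'
#' @param channels channel labels to map, default [channel_whitelist_62()]
#' @return named character vector mapping each channel to its group label
#' @export
eeg_group_map <- function(channels = channel_whitelist_62()) {
  groups <- rep("other", length(channels))
  names(groups) <- channels
  groups[channels %in% c("AF3", "AF4")] <- "AF"
  groups[channels %in% c("F7", "F5", "F3", "F4", "F6", "F8")] <- "LF"
  groups[channels %in% c("C5", "C3", "C1", "CZ", "C2", "C4", "C6")] <- "C"
  groups[channels == "FP1"] <- "FP1"
  groups[channels == "FP2"] <- "FP2"
  groups[channels == "T7"] <- "T7"
  groups[channels == "T8"] <- "T8"
  groups
}

#' Analysis time zones of the speech-preparation window
#'
#' @return data.frame with columns `zone`, `start_ms`, `end_ms` for the
#'   0-500, 500-1000 and 1000-1500 ms tertiles
#' @export
time_zones <- function() {
  data.frame(zone = c("0-500", "500-1000", "1000-1500"),
             start_ms = c(0, 500, 1000), end_ms = c(500, 1000, 1500),
             stringsAsFactors = FALSE)
}

# shape constants of one trial
N_AU_ROWS <- 17L       # action units
N_AU_FRAMES <- 87L     # 1,500 ms at 58 frames/s
N_EEG_CHANNELS <- 62L  # analysis channels
N_EEG_SAMPLES <- 192L  # 1,500 ms at 128 Hz
EMBED_DIM <- 64L

PARADIGM_LEVELS <- c("WG", "WAG", "CW", "CAW")
FLUENCY_LEVELS <- c("fluent", "stuttered", "other_disfluency", "missed")

#' Paradigm label coding
#'
#' Bijective map between paradigm codes and the pretext class integers:
#' WG=0 (word at S1), WAG=1 (word at S1 + tone at 600 ms), CW=2 (cue at S1),
#' CAW=3 (cue at S1 + tone at 600 ms).
#'
#' @param code character vector of paradigm codes
#' @return integer vector of pretext classes (0-3)
#' @export
paradigm_class <- function(code) {
  i <- match(code, PARADIGM_LEVELS)
  if (anyNA(i)) stop("unknown paradigm code: ",
                     paste(unique(code[is.na(i)]), collapse = ", "))
  i - 1L
}

#' @rdname paradigm_class
#' @param class integer vector of pretext classes (0-3)
#' @export
paradigm_code <- function(class) {
  stopifnot(all(class %in% 0:3))
  PARADIGM_LEVELS[class + 1L]
}

#' Does a paradigm include the 600 ms tone?
#' @param code paradigm code vector
#' @return logical; TRUE for WAG and CAW
#' @export
paradigm_has_tone <- function(code) paradigm_class(code) %in% c(1L, 3L)
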
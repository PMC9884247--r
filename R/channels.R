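#' Standard 64-channel montage and analysis channel groups
#'
#' The montage is a standard 64-electrode 10-10 cap layout. Seventeen
#' electrodes close to the temporal muscles, the eyes and the inion are prone
#' to muscle and ocular artifacts and are excluded from multivariate analysis;
#' the remaining 47 form the default analysis set. Two regional subsets along
#' the anterior-posterior axis are predefined: a frontal-central group
#' (13 channels) and a central-parietal group (14 channels).
#'
#' @return `montage_64()` returns the 64 channel labels; `channel_group(name)`
#'   returns the labels in a named group.
#' @param name one of `"all"`, `"default47"`, `"frontal_central"`,
#'   `"central_parietal"`, or `"excluded17"`.
#' @examples
#' length(channel_group("default47"))   # 47
#' channel_group("frontal_central")
#' @export
montage_64 <- function() {
  c("Fp1", "Fp2", "F7", "F3", "Fz", "F4", "F8",
    "FC5", "FC1", "FC2", "FC6", "T7", "C3", "Cz", "C4", "T8",
    "TP9", "CP5", "CP1", "CP2", "CP6", "TP10",
    "P7", "P3", "Pz", "P4", "P8", "Iz", "O1", "Oz", "O2", "PO10",
    "AF7", "AF3", "AF4", "AF8", "F5", "F1", "F2", "F6",
    "FT9", "FT7", "FC3", "FC4", "FT8", "FT10",
    "C5", "C1", "C2", "C6", "TP7", "CP3", "CPz", "CP4", "TP8",
    "P5", "P1", "P2", "P6", "PO7", "PO3", "POz", "PO4", "PO8")
}

excluded_17 <- function() {
  c("Fp1", "Fp2", "AF7", "AF8", "F7", "F8", "FT7", "FT8", "FT9", "FT10",
    "T7", "T8", "TP7", "TP8", "TP9", "TP10", "Iz")
}

#' @rdname montage_64
#' @export
channel_group <- function(name = c("default47", "frontal_central",
                                   "central_parietal", "all", "excluded17")) {
  name <- match.arg(name)
  switch(name,
    all = montage_64(),
    excluded17 = excluded_17(),
    default47 = setdiff(montage_64(), excluded_17()),
    frontal_central = c("FC1", "FC2", "FC3", "FC4", "FC5", "FC6",
                        "Cz", "C1", "C2", "C3", "C4", "C5", "C6"),
    central_parietal = c("Cz", "C1", "C2", "C3", "C4", "C5", "C6",
                         "CPz", "CP1", "CP2", "CP3", "CP4", "CP5", "CP6"))
}
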
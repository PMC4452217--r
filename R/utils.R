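#' @include AllClasses.R
NULL

## 32-bit FNV-1a hash of a character string; used to stamp outputs with a
## short fingerprint of the run configuration.
fnv1a32 <- function(x) {
  bytes <- as.integer(charToRaw(paste(x, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    ## h may exceed the integer range; xor only touches the low byte
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## 32-bit multiply by 16777619 without overflow: split into 16-bit halves
    lo <- h %% 65536; hi <- (h %/% 65536) %% 65536
    h <- (lo * 16777619 + (hi * 16777619 %% 65536) * 65536) %% 4294967296
  }
  ## h can exceed the integer range; format 16 bits at a time
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

#' Fingerprint of a run configuration
#'
#' Stable short hash of a configuration list, stamped (with the seed) on
#' every pipeline output so results can be traced to the settings that
#' produced them.
#'
#' @param config a list (as passed to [runPipeline()]).
#' @return 8-character hex string.
#' @export
configHash <- function(config) {
  fnv1a32(jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                           force = TRUE))
}
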
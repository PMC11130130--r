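`%||%` <- function(a, b) if (is.null(a)) b else a

# great-circle distance in km between coordinate matrices (lon, lat)
gc_dist_km <- function(p1, p2) {
  geosphere::distHaversine(p1, p2) / 1000
}

stop_named <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
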
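# Hand-built trees with exactly known geometry, used wherever a test needs
# a closed-form oracle rather than a random tree.

tube_tree <- function(radius = 0.15, length = 1) {
  seg <- data.frame(id = 1L, parent = NA_integer_, length_cm = length,
                    radius_cm = radius, sten_degree = NA_real_,
                    sten_length_cm = NA_real_, sten_pos = NA_real_,
                    wire = FALSE)
  structure(list(segments = seg, wire_diameter_cm = NA_real_,
                 measurement = list(segment_id = 1L, offset_cm = length)),
            class = "coronary_tree")
}

# root + two terminal daughters with explicit radii and lengths
bif_tree <- function(r0 = 0.15, r1 = 0.12, r2 = 0.10,
                     L0 = 1, L1 = 1, L2 = 1) {
  seg <- data.frame(id = 1:3, parent = c(NA_integer_, 1L, 1L),
                    length_cm = c(L0, L1, L2), radius_cm = c(r0, r1, r2),
                    sten_degree = NA_real_, sten_length_cm = NA_real_,
                    sten_pos = NA_real_, wire = FALSE)
  structure(list(segments = seg, wire_diameter_cm = NA_real_,
                 measurement = list(segment_id = 2L, offset_cm = L1)),
            class = "coronary_tree")
}

demo_patient <- function(map = 93.33, co = 6) list(map = map, co = co)

with_seed_local <- ffrwire:::with_seed

# exhaustive pairwise concordance (ties = 1/2): independent AUC oracle
concordance_auc <- function(pred, invasive, cutoff = 0.8) {
  pos <- which(invasive <= cutoff)
  neg <- which(invasive > cutoff)
  total <- 0
  for (i in pos) for (j in neg) {
    if (pred[i] < pred[j]) total <- total + 1
    else if (pred[i] == pred[j]) total <- total + 0.5
  }
  total / (length(pos) * length(neg))
}
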
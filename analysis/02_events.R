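#!/usr/bin/env Rscript
# Stage 2 — from photos to independent events.
#
# Applies the analysis filters (body mass > 75 g, terrestrial/scansorial
# strata), collapses photo bursts into independent events (> 1 h rule per
# species x camera), classifies each event as day / twilight / night from
# the site's sun geometry, and anchors event times to sunrise and sunset.

suppressMessages(library(camtrapdiel))

det <- read.csv("results/synthetic/detections.csv")
det$timestamp <- as.POSIXct(det$timestamp, tz = "UTC")
traits <- read.csv("results/synthetic/traits.csv")

flt <- filter_species(det, traits)
ev <- join_traits(independent_events(flt), traits)

out <- ev
out$timestamp <- format(out$timestamp, "%Y-%m-%dT%H:%M:%S")
write.csv(out, "results/events.csv", row.names = FALSE)

message("detections: ", nrow(det), " -> after species filter: ", nrow(flt),
        " -> independent events: ", nrow(ev))
message("diel categories: ",
        paste(names(table(ev$diel_category)), table(ev$diel_category),
              sep = "=", collapse = ", "))
message("events per protected area: ",
        paste(names(table(ev$protected_area)), table(ev$protected_area),
              sep = "=", collapse = ", "))
message("written to results/events.csv")
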
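# Causal assumptions for the effect of invasive Opuntia on mammal habitat
# use. One edge per line; `latent:` marks unobservable nodes, which may
# never enter an adjustment set. Edit this file (not code) to revise the
# assumed structure; the test suite re-derives adjustment sets from it.
#
# Node meanings:
#   opuntia       invasive Opuntia density at the exposure scale
#   habitat_use   mammal occupancy / detection activity at the site
#   native_plants native plant community (grass/shrub/forb/succulent cover,
#                 tree count) - a mediator of the Opuntia effect
#   livestock     livestock use of the site (proportion of days detected)
#   dist_river    distance to nearest river (m)
#   dist_road     distance to nearest road (m)
#   human_use     diffuse human activity (latent)
latent: human_use
exposure: opuntia
outcome: habitat_use

dist_road -> human_use
human_use -> livestock
human_use -> habitat_use
dist_river -> opuntia
dist_river -> native_plants
dist_river -> habitat_use
dist_road -> opuntia
dist_road -> habitat_use
livestock -> opuntia
livestock -> native_plants
livestock -> habitat_use
opuntia -> native_plants
opuntia -> habitat_use
native_plants -> habitat_use
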
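# cldmapr

Merging group-built causal loop diagrams and classifying their feedback
loops.

## The problem

Group model building (GMB) workshops produce causal loop diagrams
(CLDs): signed directed graphs in which nodes are named factors and an
edge `A → B` asserts a monotone causal influence — polarity `+1` (drawn
solid: more A drives more B) or `−1` (drawn dotted: more A drives less
B). Multi-site studies of complex public-health problems — for example,
adolescents' views of the drivers of obesity, mapped by four school
groups in each of five European countries — yield an ensemble of twenty
free-text maps that must be combined into one *master map* before its
feedback structure can be read.

`cldmapr` implements that workflow for researchers running or analysing
such studies:

1. **Hierarchical merging.** Each map is first *pruned*: variables whose
   connections go only in or only out (in-degree or out-degree 0) cannot
   sit on any loop and are removed, by default to a fixpoint. The
   largest remaining map becomes the *base map*, and every variable of
   the other maps is judged against it — discarded as a duplicate (by
   exact slug identity, an explicit synonym table, or optional
   edit-distance matching), added to the base, or parked/discarded via a
   manual decision file. Links are carried through the decision mapping
   with full provenance (the set of source group maps behind every
   element), and opposite-sign duplicate links are resolved by a logged
   majority vote over contributing maps, ties keeping the base sign.
   Group maps fold into country maps, country maps into the master.
2. **Feedback-loop analysis.** A feedback loop is a simple directed
   cycle. Its polarity is the product of its link signs: even number of
   negative links ⇒ *reinforcing* (perturbations are amplified), odd ⇒
   *balancing* (the loop resists change). The package enumerates all
   simple cycles with explicit length and count bounds, classifies them,
   profiles each loop over the nine colour-coded variable themes
   (emotional, online, physical activity, food/drink,
   economic/commercial, knowledge, home life, body weight,
   unclassified), and ranks them deterministically.
3. **Synthetic studies and fixtures.** A generator simulates the whole
   study design (countries × groups, shared vocabulary, signed random
   links, planted loops recorded as ground truth), so every stage is
   testable end to end; three packaged single-loop fixtures encode the
   classic narrative loops (commercial drivers of unhealthy diet; mental
   health and unhealthy diet; social media, body image and exercise
   motivation).

## Worked example

The `analysis/` directory holds the numbered drivers
(`01_simulate_study.R` … `04_narrative_loops.R`). The core of steps
1–3 in a session:

```r
library(cldmapr)

cfg   <- synthetic_study_config(seed = 20)   # 5 countries x 4 groups
study <- generate_study(cfg)
groups <- lapply(study, function(e) lapply(e, `[[`, "cld"))

res <- merge_hierarchical(groups)
res$master
#> <cld> master [master]: 167 variables, 502 links (391 positive, 111 negative)

sp  <- study[[1]][[1]]$planted[[1]]          # ground-truth planted loop
extract_loop(res$master, sp$nodes)
#> <feedback_loop> reinforcing (length 4, 3 themes): home_cooking -> sugary_drink_consumption_2 -> self_esteem -> stress_2
```

The planted loop — inserted into all 20 group maps — survives pruning
and both merge levels with its classification intact. On the packaged
narrative fixtures:

```r
fx <- load_narrative_fixtures()
for (l in unlist(lapply(fx, find_feedback_loops), recursive = FALSE)) print(l)
#> <feedback_loop> reinforcing (length 6, 1 themes): demand_for_unhealthy_food -> unhealthy_food_consumption -> food_company_profit -> food_company_power -> unhealthy_food_advertising -> exposure_to_unhealthy_food
#> <feedback_loop> reinforcing (length 6, 3 themes): body_image_pressure -> self_esteem -> stress -> stress_eating -> unhealthy_food_intake -> body_weight
#> <feedback_loop> reinforcing (length 7, 3 themes): influencer_exposure -> unrealistic_body_ideals -> self_esteem -> motivation_to_exercise -> physical_activity -> screen_time -> social_media_use
```

All three narrative loops are reinforcing — each is a self-perpetuating
cycle (the two negative links in the mental-health and social-media
loops cancel pairwise). `run_pipeline()` wraps the whole sequence and
writes country maps, the master (CSV, GraphML, DOT with theme colours
and dashed negative links), per-fold merge reports, the ranked loop
report and a checksummed manifest.

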
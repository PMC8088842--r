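# Schema-level constants shared across modules.

BEHAVIOR_VARS <- c("weight_input_freq", "meal_input_adherence",
                   "exercise_input_freq", "calorie_intake", "steps_k",
                   "alcohol_drinks", "over_calorie_events")

ARCHETYPES <- c("sharp decrease", "moderate decrease", "yo-yo",
                "increase", "other")

N_WEEKS <- 16L
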
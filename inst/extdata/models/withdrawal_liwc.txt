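# Withdrawal management model, word-count (LIWC-style) indicators.
# Two latent factors measured by category proportions; binary recovery outcome.
emotional_distress =~ negative_emotion + feel + anger + authentic + sexual + sad + affect + anxiety + swear
physical_pain =~ health + biology + death + body
recovery ~ emotional_distress + physical_pain
# residual covariances among co-occurring categories
negative_emotion ~~ anxiety
negative_emotion ~~ sad
negative_emotion ~~ affect
negative_emotion ~~ anger
negative_emotion ~~ feel
negative_emotion ~~ sexual
negative_emotion ~~ authentic
sexual ~~ swear
affect ~~ anxiety
sad ~~ affect
health ~~ biology
authentic ~~ feel
sad ~~ anxiety
affect ~~ feel
affect ~~ anger
anger ~~ swear
anxiety ~~ feel
anger ~~ sexual
affect ~~ swear
authentic ~~ swear
negative_emotion ~~ health
anxiety ~~ health
sad ~~ health
feel ~~ body
anger ~~ death
emotional_distress ~~ physical_pain
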
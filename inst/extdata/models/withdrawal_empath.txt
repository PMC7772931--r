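# Withdrawal management model, topic-lexicon (Empath-style) indicators.
emotional_distress =~ negative_emotion + hate + shame + suffering
physical_pain =~ pain + medical_emergency + weakness + health
recovery ~ emotional_distress + physical_pain
negative_emotion ~~ suffering
negative_emotion ~~ hate
medical_emergency ~~ health
health ~~ suffering
weakness ~~ suffering
shame ~~ hate
suffering ~~ hate
negative_emotion ~~ shame
medical_emergency ~~ suffering
pain ~~ shame
emotional_distress ~~ physical_pain
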
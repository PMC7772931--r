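# Relapse model, negated topic-lexicon indicators.
low_positive_emotion =~ joy_prime + zest_prime + cheerfulness_prime + positive_emotion_prime
low_career =~ white_collar_job_prime + blue_collar_job_prime + office_prime
relapse ~ low_positive_emotion + low_career + urban_prime
joy_prime ~~ zest_prime
joy_prime ~~ cheerfulness_prime
white_collar_job_prime ~~ blue_collar_job_prime
white_collar_job_prime ~~ office_prime
low_positive_emotion ~~ low_career
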
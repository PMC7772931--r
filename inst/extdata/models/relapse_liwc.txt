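# Relapse model, negated (prime) word-count indicators.
anti_social =~ friend_prime + we_prime + shehe_prime + you_prime + male_prime + female_prime
relapse ~ anti_social + religion_prime + motion_prime + tone_prime
shehe_prime ~~ female_prime
friend_prime ~~ you_prime
you_prime ~~ female_prime
friend_prime ~~ shehe_prime
shehe_prime ~~ you_prime
shehe_prime ~~ male_prime
friend_prime ~~ male_prime
anti_social ~~ tone_prime
anti_social ~~ religion_prime
motion_prime ~~ tone_prime
anti_social ~~ motion_prime
we_prime ~~ tone_prime
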
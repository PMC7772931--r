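# Recovery-efforts model from normalized forum-activity indicators.
mpwb =~ act_fitness + act_meditation + act_bodyweightfitness + act_running + act_yoga + act_gainit
career =~ act_jobs + act_entrepreneur + act_careerguidance + act_resumes
relationships =~ act_relationship_advice + act_relationships + act_parenting + act_childfree
recovery ~ mpwb + relationships + career
act_careerguidance ~~ act_resumes
act_yoga ~~ act_bodyweightfitness
act_entrepreneur ~~ act_careerguidance
act_entrepreneur ~~ act_resumes
act_fitness ~~ act_yoga
relationships ~~ mpwb
relationships ~~ career
mpwb ~~ career
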
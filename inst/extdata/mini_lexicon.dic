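%
1	negative_emotion
2	sad
3	anger
4	anxiety
5	feel
6	affect
7	swear
8	sexual
9	biology
10	death
11	health
12	body
13	friend
14	we
15	shehe
16	you
17	male
18	female
19	motion
20	religion
21	tone
22	hate
23	shame
24	suffering
25	pain
26	medical_emergency
27	weakness
28	joy
29	zest
30	cheerfulness
31	positive_emotion
32	white_collar_job
33	blue_collar_job
34	office
35	urban
36	emotional
37	swearing_terms
%
ache	5
addiction	11
afraid	4
agony	24
aids	8
analyst	32
angry	36
annoyed	3
anxious	4
apartment	35
argh	3
awful	1	22
bad	25
bartender	33
battle	3
bestie	13
bike	19
bless*	20
blood	9	12
body	9
boy*	17
brain	9
buddy	13
bury	10
calm	31
cheer	28
cheerful	30
church	20
city	35
clerk	33
climb*	19
clinic	11
coffin	10
companion	13
cramp*	25
crap	7
cried	6
crying	2
curse	37
dad	17
damn	3	7	37
dead	10
delight*	28
depress*	2	6
desk	34
destroy	3
die*	10
disgust	22
dislike	22
dose	11
dosing	9
downtown	35
drug*	11
dumb	7
eager*	29
emaciated	27
embarrass*	23
empty	2
energetic	29
engineer	32
enthusiasm	29
epilepsy	26
er	26
excite*	29
excruciating	24
faith	20
father	17
fatigue	27
fax	34
fearful	4
feeling	5
feels	5
fever	26
flu	11	26
frail	27
friend*	13
fuck*	7
fun	28
furious	3
girl*	18
glad	21
gleeful	30
god	20
going	19
good	21	31
grateful	31
grave	10
great	21
grief	2
hand	12
happy	6	21	31
hate	3	22
he	15	17
headache	25
hell	7	37
her	15	18
hers	15	18
herself	15
him	15	17
himself	15
his	15	17
holy	20
hope*	21	31
horny	8
hurt	1	5
husband	17
job	32
jog*	19
jolly	30
joy*	28
kick	25
kill	3	10	25
killing	6
laptop	34
laugh*	28
lawyer	32
lets	14
lifeless	26
live	9
loathe	22
love*	21	31
low	2
mad	36
maid	33
man	17
manager	32	34
mate	13
meeting	34
men	17
merry	30
metro	35
miserable	1	36
misery	4
mom	18
mother	18
mouth	9	12
moving	19
muscle*	12
naked	8
nasty	1	22
nausea*	11
nerve*	9
nice	21
numb	5
nurse	32
od	10
our*	14
ourselves	14
overdose	26
pain	5	11	25
painful	5	6	24
pal	13
panic	4
paranoia	4
pissed	7
pitiful	23
pizzeria	33
plumber	33
pray*	20
printing	34
proud	31
rant	36
reception	34
regret	24
retard	37
ride*	19
run*	19
sad	2
salary	32
scared	6
screw*	7
screwed	8
seizure	26
serving	33
sex*	8
shaky	27
shame*	1
shameful	23
she	15	18
shit*	7	37
sick	11	25
skyscraper	35
slay	10
sleep	9	12
smile*	28
sore	25
sorrowful	23
stomach	12
subway	35
suffer	23
suffering	24
suicidal	36
sunny	30
swear	37
sweat*	12
tears	24
terrible	1
terror	23
thrill*	29
tired	2
torture	24
touch	5
traffic	35
trauma	26
ugly	1
uncomfortable	1
uneasiness	23
unhappy	36
unplanned	8
unsure	4	6
upbeat	30
urinary	12
us	14
useless	2
waiter	33
walk*	19
we	14
weak*	27
weakening	27
weariness	27
wife	18
woman	18
women	18
wonderful	21
workplace	34
worry*	4
worse	22
worship*	20
worst	6
yall	16
you	16
your*	16
yourself	16
zest	29
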
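name	feature_class	major	place	manner	voicing	height	backness	rounding
voiced	voicing	consonant			voiced
voiceless	voicing	consonant			voiceless
nasal	manner	consonant		nasal
stop	manner	consonant		stop
continuant	manner	consonant		continuant
vibrant	manner	consonant		vibrant
lateral	manner	consonant		lateral
voiced nasal	manner×voicing	consonant		nasal	voiced
voiceless nasal	manner×voicing	consonant		nasal	voiceless
voiced stop	manner×voicing	consonant		stop	voiced
voiceless stop	manner×voicing	consonant		stop	voiceless
voiced continuant	manner×voicing	consonant		continuant	voiced
voiceless continuant	manner×voicing	consonant		continuant	voiceless
voiced vibrant	manner×voicing	consonant		vibrant	voiced
voiceless vibrant	manner×voicing	consonant		vibrant	voiceless
voiced lateral	manner×voicing	consonant		lateral	voiced
voiceless lateral	manner×voicing	consonant		lateral	voiceless
labial	place	consonant	labial
alveolar	place	consonant	alveolar
palatal	place	consonant	palatal
velar	place	consonant	velar
glottal	place	consonant	glottal
voiced labial	place×voicing	consonant	labial		voiced
voiceless labial	place×voicing	consonant	labial		voiceless
voiced alveolar	place×voicing	consonant	alveolar		voiced
voiceless alveolar	place×voicing	consonant	alveolar		voiceless
voiced palatal	place×voicing	consonant	palatal		voiced
voiceless palatal	place×voicing	consonant	palatal		voiceless
voiced velar	place×voicing	consonant	velar		voiced
voiceless velar	place×voicing	consonant	velar		voiceless
voiced glottal	place×voicing	consonant	glottal		voiced
voiceless glottal	place×voicing	consonant	glottal		voiceless
high vowel	height	vowel				high
mid vowel	height	vowel				mid
low vowel	height	vowel				low
front vowel	backness	vowel					front
central vowel	backness	vowel					central
back vowel	backness	vowel					back
rounded vowel	rounding	vowel						rounded
unrounded vowel	rounding	vowel						unrounded
high front vowel	height×backness	vowel				high	front
high central vowel	height×backness	vowel				high	central
high back vowel	height×backness	vowel				high	back
mid front vowel	height×backness	vowel				mid	front
mid central vowel	height×backness	vowel				mid	central
mid back vowel	height×backness	vowel				mid	back
low front vowel	height×backness	vowel				low	front
low central vowel	height×backness	vowel				low	central
low back vowel	height×backness	vowel				low	back
front rounded vowel	backness×rounding	vowel					front	rounded
front unrounded vowel	backness×rounding	vowel					front	unrounded
back rounded vowel	backness×rounding	vowel					back	rounded
back unrounded vowel	backness×rounding	vowel					back	unrounded
low front rounded vowel	height×backness×rounding	vowel				low	front	rounded
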
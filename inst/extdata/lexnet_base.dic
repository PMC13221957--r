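%
1	pos_tone
2	neg_tone
3	social
4	negate
5	ppron
6	ipron
7	total_pronouns
8	pron_i
9	pron_we
10	pron_you
11	pron_shehe
12	pron_they
13	article
14	prep
15	auxverb
16	conj
17	adverb
18	exclusive
%
good	1
happy	1
love	1
loved	1
nice	1
great	1
hope*	1
joy*	1
calm	1
glad	1
proud	1
fun	1
beautiful	1
wonderful	1
support*	1
comfort*	1
relief	1
peaceful	1
kind	1
warm	1
better	1
safe	1
grateful	1
laugh*	1
smile*	1
bad	2
sad	2
hurt*	2
hate*	2
fear*	2
afraid	2
terrible	2
awful	2
worr*	2
alone	2
lonel*	2
pain	2
painful	2
cry	2
cried	2
crying	2
angry	2
anger	2
scared	2
horrible	2
lost	2
dark	2
miserable	2
suffer*	2
ashamed	2
guilt*	2
friend*	3
family	3
families	3
mother	3
father	3
parent*	3
people	3
talk*	3
social	3
together	3
community	3
neighbor*	3
brother	3
sister	3
doctor*	3
nurse*	3
visit*	3
conversation*	3
meet*	3
group*	3
others	3
husband	3
wife	3
son	3
daughter	3
team	3
not	4
no	4
never	4
none	4
cannot	4
nothing	4
don't	4
didn't	4
doesn't	4
isn't	4
wasn't	4
aren't	4
weren't	4
can't	4
couldn't	4
won't	4
wouldn't	4
shouldn't	4
haven't	4
hasn't	4
hadn't	4
i	5	7	8
me	5	7	8
my	5	7	8
mine	5	7	8
myself	5	7	8
we	5	7	9
us	5	7	9
our	5	7	9
ours	5	7	9
ourselves	5	7	9
you	5	7	10
your	5	7	10
yours	5	7	10
yourself	5	7	10
yourselves	5	7	10
she	5	7	11
her	5	7	11
hers	5	7	11
herself	5	7	11
he	5	7	11
him	5	7	11
his	5	7	11
himself	5	7	11
they	5	7	12
them	5	7	12
their	5	7	12
theirs	5	7	12
themselves	5	7	12
it	6	7
its	6	7
itself	6	7
this	6	7
that	6	7
these	6	7
those	6	7
something	6	7
anything	6	7
everything	6	7
someone	6	7
anyone	6	7
everyone	6	7
somebody	6	7
anybody	6	7
everybody	6	7
who	6	7
what	6	7
which	6	7
a	13
an	13
the	13
in	14
on	14
at	14
with	14
from	14
into	14
about	14
over	14
under	14
through	14
between	14
during	14
before	14
after	14
against	14
toward	14
towards	14
of	14
for	14
by	14
within	14
am	15
is	15
are	15
was	15
were	15
be	15
been	15
being	15
have	15
has	15
had	15
do	15
does	15
did	15
will	15
would	15
can	15
could	15
should	15
may	15
might	15
must	15
shall	15
and	16
but	16
or	16
because	16
so	16
if	16
while	16
although	16
though	16
since	16
whereas	16
unless	16
very	17
really	17
just	17
quite	17
too	17
also	17
often	17
always	17
sometimes	17
again	17
soon	17
almost	17
maybe	17
perhaps	17
rather	17
still	17
even	17
now	17
then	17
here	17
there	17
except	18
without	18
however	18
besides	18
apart	18
excluding	18
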
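# English function-word stop list, one word per line.
# Contractions are stored apostrophe-free because the normalizer deletes
# apostrophes before tokenizing. Negations (no, not, never, nor) are kept
# OUT of this list: they carry meaning for health-claim patterns.
i
me
my
myself
we
our
ours
ourselves
you
youre
youve
youll
youd
your
yours
yourself
yourselves
he
him
his
himself
she
shes
her
hers
herself
it
its
itself
they
them
their
theirs
themselves
what
which
who
whom
this
that
thatll
these
those
am
is
are
was
were
be
been
being
have
has
had
having
do
does
did
doing
a
an
the
and
but
if
or
because
as
until
while
of
at
by
for
with
about
against
between
into
through
during
before
after
above
below
to
from
up
down
in
out
on
off
over
under
again
further
then
once
here
there
when
where
why
how
all
any
both
each
few
more
most
other
some
such
only
own
same
so
than
too
very
s
t
can
will
just
dont
should
shouldve
now
d
ll
m
o
re
ve
y
aint
arent
couldnt
didnt
doesnt
hadnt
hasnt
havent
isnt
ma
mightnt
mustnt
neednt
shant
shouldnt
wasnt
werent
wont
wouldnt
im
ive
id
ill
hes
hed
hell
weve
wed
well
theyre
theyve
theyd
theyll
whats
whos
thats
heres
theres
wheres
whens
whys
hows
lets
cant
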